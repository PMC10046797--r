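# Brute-force optimality oracle.
#
# With the sign binaries (one per gene) and the relative order of the class
# intervals fixed, the model collapses to a linear program. Enumerating all
# 2^M sign vectors and all C! interval orderings and taking the best LP
# optimum therefore yields the certified global optimum. Each LP is solved
# with the bundled pure-R two-phase simplex (R/simplex.R), so this route
# shares no code with the HiGHS branch-and-bound backend it is used to
# check.

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Solve one fixed-binaries LP.
# X: genes x samples; y_idx: class index per sample; sigma: +/-1 per gene;
# ord: class indices from lowest to highest interval position.
# LP variables (all >= 0): w(M), LOp(C), LOn(C), UPp(C), UPn(C), D(S).
fixed_assignment_lp <- function(X, y_idx, n_classes, sigma, ord, eps) {
  M <- nrow(X); S <- ncol(X); C <- n_classes
  i_w <- seq_len(M)
  i_LOp <- M + seq_len(C);      i_LOn <- M + C + seq_len(C)
  i_UPp <- M + 2L * C + seq_len(C); i_UPn <- M + 3L * C + seq_len(C)
  i_D <- M + 4L * C + seq_len(S)
  n <- M + 4L * C + S

  V <- sigma * X                      # activity coefficients per sample
  n_ge <- (C - 1L) + C + 2L * S
  A2 <- matrix(0, n_ge, n)
  b2 <- numeric(n_ge)
  r <- 0L
  if (C > 1L) {
    for (j in seq_len(C - 1L)) {      # LO[above] - UP[below] >= eps
      lo <- ord[j + 1L]; up <- ord[j]
      r <- r + 1L
      A2[r, c(i_LOp[lo], i_LOn[lo], i_UPp[up], i_UPn[up])] <- c(1, -1, -1, 1)
      b2[r] <- eps
    }
  }
  for (cc in seq_len(C)) {            # UP_c - LO_c >= eps
    r <- r + 1L
    A2[r, c(i_UPp[cc], i_UPn[cc], i_LOp[cc], i_LOn[cc])] <- c(1, -1, -1, 1)
    b2[r] <- eps
  }
  for (s in seq_len(S)) {             # D_s >= LO_cs - a_s and a_s - UP_cs
    cs <- y_idx[s]
    r <- r + 1L
    A2[r, i_w] <- V[, s]
    A2[r, c(i_D[s], i_LOp[cs], i_LOn[cs])] <- c(1, -1, 1)
    r <- r + 1L
    A2[r, i_w] <- -V[, s]
    A2[r, c(i_D[s], i_UPp[cs], i_UPn[cs])] <- c(1, 1, -1)
  }
  obj <- numeric(n); obj[i_D] <- 1
  A <- rbind(A2, rep(0, n))
  A[n_ge + 1L, i_w] <- 1
  fit <- simplex_lp(obj, A, c(b2, 1),
                    c(rep(">=", n_ge), "="))
  if (fit$status != "optimal") return(NULL)
  x <- fit$x
  list(value = fit$value,
       w = sigma * x[i_w],
       LO = x[i_LOp] - x[i_LOn],
       UP = x[i_UPp] - x[i_UPn],
       D = x[i_D])
}

enumerate_optimum <- function(X, y, eps, keep_solution = FALSE) {
  M <- nrow(X); C <- nlevels(y)
  y_idx <- as.integer(y)
  best <- NULL
  orderings <- perms(seq_len(C))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), M)))
  for (i in seq_len(nrow(signs))) {
    sigma <- as.numeric(signs[i, ])
    for (ord in orderings) {
      sol <- fixed_assignment_lp(X, y_idx, C, sigma, ord, eps)
      if (is.null(sol)) next
      if (is.null(best) || sol$value < best$value) {
        best <- if (keep_solution) c(sol, list(sigma = sigma, ord = ord))
                else list(value = sol$value)
      }
    }
  }
  if (is.null(best)) stop("enumeration found no feasible assignment",
                          call. = FALSE)
  best
}

#' Certified global optimum by exhaustive enumeration
#'
#' Enumerates every assignment of the sign binaries and every relative
#' ordering of the class intervals, solves the resulting linear program
#' for each, and returns the best objective. Intended as an optimality
#' certificate for small instances; the guard limits the
#' `2^M * C!` LP solves.
#'
#' @inheritParams solve_dioptra
#' @return The minimal total violation distance (a single number).
#' @export
brute_force_optimum <- function(expr, labels, config = model_config()) {
  validate_expression(expr)
  y <- labels_for(labels, colnames(expr))
  if (nrow(expr) > 6L || nlevels(y) > 3L) {
    stop(sprintf("instance too large for enumeration (%d genes, %d classes; limits 6 and 3)",
                 nrow(expr), nlevels(y)), call. = FALSE)
  }
  enumerate_optimum(expr, y, config$epsilon)$value
}

# Full-solution variant used by the "enumerate" solver backend.
enumerate_solve <- function(X, y, config) {
  if (nrow(X) > 6L || nlevels(y) > 3L) {
    stop("the enumerate backend is limited to 6 genes and 3 classes; ",
         "use the highs backend", call. = FALSE)
  }
  best <- enumerate_optimum(X, y, config$epsilon, keep_solution = TRUE)
  classes <- levels(y)
  C <- length(classes)
  w <- best$w
  rp <- pmax(w, 0); rn <- pmax(-w, 0)
  names(rp) <- names(rn) <- rownames(X)
  intervals <- cbind(LO = best$LO, UP = best$UP)
  rownames(intervals) <- classes
  Y <- numeric(0)
  if (C > 1L) {
    pos <- order(best$ord)             # rank of each class on the axis
    pairs <- utils::combn(C, 2L)
    Y <- as.numeric(pos[pairs[2L, ]] > pos[pairs[1L, ]])
    cp <- utils::combn(classes, 2L)
    names(Y) <- paste(cp[1L, ], cp[2L, ], sep = "<")
  }
  activities <- drop(crossprod(X, w))
  names(activities) <- colnames(X)
  D <- best$D
  names(D) <- colnames(X)
  structure(list(
    gene_ids = rownames(X), rp = rp, rn = rn,
    L = as.numeric(best$sigma > 0), signed_weights = rp - rn,
    intervals = intervals, Y = Y, activities = activities,
    violations = D, objective = best$value, status = "OPTIMAL",
    relative_gap = 0, classes = classes, epsilon = config$epsilon,
    message = "exhaustive enumeration"),
    class = "pathway_solution")
}
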