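#' Model configuration for the pathway-activity MILP
#'
#' Collects the tunable constants of the optimisation model and solver.
#'
#' @param epsilon Minimum class-interval separation and minimum interval
#'   width, on the activity scale (same units as expression). Must be
#'   positive; default `1e-3`, far below typical FPKM magnitudes yet well
#'   above solver feasibility tolerance.
#' @param big_M Deactivation constant for the interval-ordering
#'   constraints, or `"auto"` (default) to derive a tight value per
#'   pathway from the expression scale (see [resolve_big_M()]).
#' @param time_limit_s Solver time limit per model, seconds; default 200.
#'   An incumbent found within the limit is returned as a `FEASIBLE`
#'   solution with its relative gap.
#' @param relative_gap_target Relative MIP gap at which the solver may
#'   stop; default 0 (prove optimality).
#' @param solver_backend `"highs"` (default; HiGHS branch-and-bound via
#'   the bundled bridge) or `"enumerate"` (exhaustive enumeration plus LP,
#'   only for very small instances).
#' @param numeric_tolerance Tolerance used when validating returned
#'   solutions; default `1e-6`.
#' @param random_seed Optional integer recorded in provenance output.
#' @return An object of class `dioptra_config`.
#' @export
model_config <- function(epsilon = 1e-3, big_M = "auto", time_limit_s = 200,
                         relative_gap_target = 0, solver_backend = "highs",
                         numeric_tolerance = 1e-6, random_seed = NULL) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(time_limit_s), time_limit_s > 0,
            is.numeric(relative_gap_target), relative_gap_target >= 0,
            is.numeric(numeric_tolerance), numeric_tolerance > 0)
  solver_backend <- match.arg(solver_backend, c("highs", "enumerate"))
  if (!identical(big_M, "auto")) {
    stopifnot(is.numeric(big_M), length(big_M) == 1L)
    if (big_M <= 2 * epsilon) {
      stop("big_M must exceed 2 * epsilon", call. = FALSE)
    }
  }
  structure(list(epsilon = epsilon, big_M = big_M,
                 time_limit_s = time_limit_s,
                 relative_gap_target = relative_gap_target,
                 solver_backend = solver_backend,
                 numeric_tolerance = numeric_tolerance,
                 random_seed = random_seed),
            class = "dioptra_config")
}

#' @export
print.dioptra_config <- function(x, ...) {
  cat("dioptra model configuration\n")
  cat(sprintf("  epsilon:        %g\n", x$epsilon))
  cat(sprintf("  big_M:          %s\n",
              if (identical(x$big_M, "auto")) "auto (per pathway)"
              else format(x$big_M)))
  cat(sprintf("  time limit:     %g s\n", x$time_limit_s))
  cat(sprintf("  gap target:     %g\n", x$relative_gap_target))
  cat(sprintf("  backend:        %s\n", x$solver_backend))
  invisible(x)
}

#' Resolve the big-M constant for an expression submatrix
#'
#' Because the absolute gene weights sum to one, every attainable
#' activity satisfies `|pa_s| <= max|G|`; `2 * max|G| + 3 * epsilon`
#' therefore dominates any attainable activity spread and is a safe
#' deactivation scale for the interval-ordering constraints.
#'
#' @param expr Expression matrix (or submatrix) the model will see.
#' @param epsilon Separation constant of the model.
#' @return A single positive number.
#' @export
resolve_big_M <- function(expr, epsilon) {
  stopifnot(is.numeric(expr), length(expr) >= 1L,
            is.numeric(epsilon), epsilon > 0)
  2 * max(abs(expr)) + 3 * epsilon
}

# Internally consistent (bound, deactivation constant) pair. With interval
# variables bounded at +/-B, constraint (upper_k + eps <= lower_c + U) must
# be inactive for every feasible corner when its binary deactivates it,
# which requires U >= 2B + eps. "auto" derives B from the expression scale
# with enough slack ((2C+1) * eps) that C stacked intervals of minimal
# width always fit; a numeric big_M is taken as U with B back-solved.
milp_scaling <- function(gmax, n_classes, epsilon, big_M) {
  if (identical(big_M, "auto")) {
    B <- gmax + (2 * n_classes + 1) * epsilon
    U <- 2 * B + epsilon
  } else {
    U <- big_M
    B <- (U - epsilon) / 2
  }
  list(bound = B, U = U)
}

# Build the MILP for one pathway in sparse triplet form.
#
# X: genes x samples (restricted to the pathway), y: factor over colnames(X).
# Variable layout: rp(M) rn(M) LO(C) UP(C) D(S) L(M) Y(P), P = C(C-1)/2.
# The activity pa_s = sum_m G_sm (rp_m - rn_m) is substituted into the
# violation rows rather than carried as a variable.
build_dioptra_problem <- function(X, y, config) {
  M <- nrow(X); S <- ncol(X)
  classes <- levels(y)
  C <- length(classes)
  P <- (C * (C - 1L)) %/% 2L
  eps <- config$epsilon
  sc <- milp_scaling(max(abs(X)), C, eps, config$big_M)
  U <- sc$U; B <- sc$bound

  i_rp <- seq_len(M)
  i_rn <- M + seq_len(M)
  i_LO <- 2L * M + seq_len(C)
  i_UP <- 2L * M + C + seq_len(C)
  i_D  <- 2L * M + 2L * C + seq_len(S)
  i_L  <- 2L * M + 2L * C + S + seq_len(M)
  i_Y  <- 2L * M + 2L * C + S + M + seq_len(P)
  n <- 2L * M + 2L * C + S + M + P

  ti <- list(); tj <- list(); tx <- list(); rhs <- list()
  row <- 0L
  add_row <- function(j, x, b) {
    row <<- row + 1L
    ti[[row]] <<- rep.int(row, length(j))
    tj[[row]] <<- j
    tx[[row]] <<- x
    rhs[[row]] <<- b
  }

  # sign-consistency linking: rp_m <= L_m, rn_m <= 1 - L_m
  for (m in seq_len(M)) {
    add_row(c(i_rp[m], i_L[m]), c(1, -1), 0)
    add_row(c(i_rn[m], i_L[m]), c(1, 1), 1)
  }
  # pairwise non-overlap with big-M switching, generated for k < c in the
  # deterministic class sort order
  pairs <- if (P > 0L) utils::combn(C, 2L) else matrix(integer(), 2L, 0L)
  for (p in seq_len(P)) {
    k <- pairs[1L, p]; cc <- pairs[2L, p]
    add_row(c(i_UP[k], i_LO[cc], i_Y[p]), c(1, -1, U), U - eps)
    add_row(c(i_UP[cc], i_LO[k], i_Y[p]), c(1, -1, -U), -eps)
  }
  # minimum interval width
  for (cc in seq_len(C)) {
    add_row(c(i_LO[cc], i_UP[cc]), c(1, -1), -eps)
  }
  # violation distance rows, activity substituted in
  y_idx <- as.integer(y)
  for (s in seq_len(S)) {
    g <- X[, s]
    nz <- which(g != 0)
    cs <- y_idx[s]
    add_row(c(i_rp[nz], i_rn[nz], i_UP[cs], i_D[s]),
            c(g[nz], -g[nz], -1, -1), 0)
    add_row(c(i_rp[nz], i_rn[nz], i_LO[cs], i_D[s]),
            c(-g[nz], g[nz], 1, -1), 0)
  }

  lb <- numeric(n)
  ub <- rep.int(Inf, n)
  ub[c(i_rp, i_rn)] <- 1
  lb[c(i_LO, i_UP)] <- -B
  ub[c(i_LO, i_UP)] <- B
  ub[i_D] <- 2 * B
  ub[c(i_L, i_Y)] <- 1
  # symmetry break: every solution has a mirror twin under sign flip plus
  # interval reflection, so the first gene's sign binary can be fixed
  lb[i_L[1L]] <- 1

  obj <- numeric(n)
  obj[i_D] <- 1
  integrality <- numeric(n)
  integrality[c(i_L, i_Y)] <- 1

  list(n = n, obj = obj,
       A_ub = list(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                   nrow = row),
       b_ub = unlist(rhs),
       A_eq = list(i = rep.int(1L, 2L * M), j = c(i_rp, i_rn),
                   x = rep.int(1, 2L * M), nrow = 1L),
       b_eq = 1,
       lb = lb, ub = ub, integrality = integrality,
       index = list(rp = i_rp, rn = i_rn, LO = i_LO, UP = i_UP,
                    D = i_D, L = i_L, Y = i_Y),
       meta = list(gene_ids = rownames(X), sample_ids = colnames(X),
                   classes = classes, epsilon = eps, U = U, bound = B))
}
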