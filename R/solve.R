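#' Solve the pathway-activity MILP for one pathway
#'
#' Learns signed gene weights `w_m = rp_m - rn_m` (absolute weights summing
#' to one, at most one of `rp_m`, `rn_m` positive per gene) together with
#' one activity interval `[LO_c, UP_c]` per phenotype class, such that the
#' intervals are pairwise separated by at least `epsilon` and the total
#' violation distance -- the distance from each training sample's activity
#' `pa_s = sum_m G_sm w_m` to its own class interval -- is minimal.
#'
#' @param expr Expression matrix restricted to the pathway's member genes
#'   (genes x samples); every column must be labelled.
#' @param labels Phenotype labels covering the samples of `expr` (named
#'   factor or vector, see [phenotype_labels()]).
#' @param config A [model_config()].
#' @return An object of class `pathway_solution`: gene weights (`rp`, `rn`,
#'   `signed_weights`, sign binaries `L`), per-class `intervals` (LO/UP),
#'   ordering binaries `Y`, training `activities` and `violations`, the
#'   `objective` (sum of violation distances), solver `status`
#'   (`"OPTIMAL"`, `"FEASIBLE"` or `"NO_SOLUTION"`) and `relative_gap`.
#' @export
solve_dioptra <- function(expr, labels, config = model_config()) {
  validate_expression(expr)
  if (nrow(expr) == 0L) {
    stop("no pathway genes present in the expression matrix", call. = FALSE)
  }
  y <- labels_for(labels, colnames(expr))
  if (config$solver_backend == "enumerate") {
    return(enumerate_solve(expr, y, config))
  }
  problem <- build_dioptra_problem(expr, y, config)
  res <- highs_solve_batch(list(problem), config)[[1L]]
  extract_solution(problem, res, expr, config)
}

#' Fit the pathway-activity model for a whole gene-set collection
#'
#' Builds one MILP per pathway (restricted to the member genes present in
#' `expr`) and solves them as a single solver batch. Pathways with no
#' member gene in the matrix are skipped with a warning and recorded in
#' the `"skipped"` attribute.
#'
#' @inheritParams solve_dioptra
#' @param gene_sets Named list of member-gene character vectors
#'   (see [read_gmt()]).
#' @return Named list of `pathway_solution` objects (class `dioptra_fit`).
#' @export
fit_dioptra <- function(expr, gene_sets, labels, config = model_config()) {
  validate_expression(expr)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  y <- labels_for(labels, colnames(expr))
  members <- lapply(gene_sets, intersect, x = rownames(expr))
  keep <- lengths(members) > 0L
  if (!all(keep)) {
    warning(sprintf("skipping %d pathway(s) with no genes in the matrix: %s",
                    sum(!keep),
                    paste(names(members)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  members <- members[keep]
  problems <- lapply(members, function(g) {
    build_dioptra_problem(expr[g, , drop = FALSE], y, config)
  })
  fits <- list()
  if (length(problems)) {
    res <- highs_solve_batch(problems, config)
    fits <- mapply(function(p, r, g) {
      extract_solution(p, r, expr[g, , drop = FALSE], config)
    }, problems, res, members, SIMPLIFY = FALSE)
  }
  names(fits) <- names(members)
  structure(fits, class = "dioptra_fit",
            skipped = names(gene_sets)[!keep])
}

# Turn one raw backend result into a pathway_solution.
extract_solution <- function(problem, res, X, config) {
  idx <- problem$index
  meta <- problem$meta
  status <- map_solver_status(res)
  if (status == "NO_SOLUTION") {
    return(structure(list(
      gene_ids = meta$gene_ids, rp = NULL, rn = NULL, L = NULL,
      signed_weights = NULL, intervals = NULL, Y = NULL,
      activities = NULL, violations = NULL, objective = NA_real_,
      status = status, relative_gap = NA_real_,
      classes = meta$classes, epsilon = meta$epsilon,
      message = res$message %||% "no incumbent within the time limit"),
      class = "pathway_solution"))
  }
  x <- as.numeric(unlist(res$x))
  rp <- pmin(pmax(x[idx$rp], 0), 1)
  rn <- pmin(pmax(x[idx$rn], 0), 1)
  names(rp) <- names(rn) <- meta$gene_ids
  w <- rp - rn
  intervals <- cbind(LO = x[idx$LO], UP = x[idx$UP])
  rownames(intervals) <- meta$classes
  Y <- x[idx$Y]
  if (length(Y)) {
    pairs <- utils::combn(meta$classes, 2L)
    names(Y) <- paste(pairs[1L, ], pairs[2L, ], sep = "<")
    Y <- round(Y)
  }
  activities <- drop(crossprod(X, w))
  names(activities) <- meta$sample_ids
  violations <- pmax(x[idx$D], 0)
  names(violations) <- meta$sample_ids
  gap <- res$mip_gap
  gap <- if (status == "OPTIMAL") 0 else min(max(gap %||% NA_real_, 0), 1)
  structure(list(
    gene_ids = meta$gene_ids, rp = rp, rn = rn, L = round(x[idx$L]),
    signed_weights = w, intervals = intervals, Y = Y,
    activities = activities, violations = violations,
    objective = res$objective, status = status, relative_gap = gap,
    classes = meta$classes, epsilon = meta$epsilon,
    message = res$message %||% ""),
    class = "pathway_solution")
}

#' @export
print.pathway_solution <- function(x, ...) {
  cat(sprintf("pathway_solution: %d gene(s), %d class(es), status %s\n",
              length(x$gene_ids), length(x$classes), x$status))
  if (x$status != "NO_SOLUTION") {
    cat(sprintf("  objective (sum of violation distances): %.6g\n",
                x$objective))
    cat(sprintf("  relative gap: %.4g\n", x$relative_gap))
    nz <- which(abs(x$signed_weights) > 1e-9)
    top <- nz[order(-abs(x$signed_weights[nz]))]
    top <- utils::head(top, 5L)
    if (length(top)) {
      cat("  leading weights:",
          paste(sprintf("%s=%.3f", x$gene_ids[top],
                        x$signed_weights[top]), collapse = ", "), "\n")
    }
  } else {
    cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' Compute pathway activities from fitted gene weights
#'
#' Applies the weighted linear combination `pa_s = sum_m G_sm w_m`
#' identically to training and unseen samples.
#'
#' @param weights Named numeric vector of signed gene weights.
#' @param expr Expression matrix containing at least those genes.
#' @return Named numeric vector of activities, one per sample of `expr`.
#' @export
compute_pathway_activity <- function(weights, expr) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  validate_expression(expr)
  missing <- setdiff(names(weights), rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- drop(crossprod(expr[names(weights), , drop = FALSE], weights))
  names(out) <- colnames(expr)
  out
}

#' Pathway x sample activity profile from a fitted collection
#'
#' @param fit A `dioptra_fit` (or plain list of `pathway_solution`s,
#'   named by pathway).
#' @param expr Expression matrix to score (training or unseen samples).
#' @return Numeric matrix, pathways x samples; rows for pathways whose
#'   solve produced no solution are `NA`.
#' @export
activity_profile <- function(fit, expr) {
  validate_expression(expr)
  stopifnot(is.list(fit), !is.null(names(fit)))
  out <- matrix(NA_real_, nrow = length(fit), ncol = ncol(expr),
                dimnames = list(names(fit), colnames(expr)))
  for (pw in names(fit)) {
    sol <- fit[[pw]]
    if (!is.null(sol$signed_weights)) {
      out[pw, ] <- compute_pathway_activity(sol$signed_weights, expr)
    }
  }
  out
}
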