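# Reference pathway-activity scores used for comparison.

#' Mean-expression pathway activity
#'
#' The simplest pathway score: the arithmetic mean of the member genes'
#' expression in each sample.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_set Character vector of member gene ids.
#' @return Named numeric vector of activities, one per sample.
#' @export
mean_activity <- function(expr, gene_set) {
  validate_expression(expr)
  genes <- intersect(gene_set, rownames(expr))
  if (!length(genes)) {
    stop("no member genes present in the expression matrix", call. = FALSE)
  }
  colMeans(expr[genes, , drop = FALSE])
}

#' Fit a first-principal-component pathway activity model
#'
#' Centres each member gene by its training mean and takes the first
#' eigenvector of the training covariance as the loading vector. The
#' loading has unit Euclidean norm and its sign is fixed by forcing the
#' largest-magnitude entry positive. Fitting on training folds only and
#' projecting held-out samples with [pca_activity_apply()] keeps the
#' score blind to test data.
#'
#' @param expr_train Training expression matrix (genes x samples, >= 2
#'   samples).
#' @param gene_set Character vector of member gene ids.
#' @param scale. Standardise genes to unit variance before the
#'   decomposition; default `FALSE` (centring only).
#' @return A `baseline_model` with fields `method`, `genes`, `center`,
#'   `loading` (and `scale` when requested).
#' @export
pca_activity_fit <- function(expr_train, gene_set, scale. = FALSE) {
  validate_expression(expr_train)
  genes <- intersect(gene_set, rownames(expr_train))
  if (!length(genes)) {
    stop("no member genes present in the expression matrix", call. = FALSE)
  }
  if (ncol(expr_train) < 2L) {
    stop("PCA fit needs >= 2 training samples", call. = FALSE)
  }
  X <- t(expr_train[genes, , drop = FALSE])   # samples x genes
  if (all(apply(X, 2L, stats::var) < .Machine$double.eps)) {
    stop("degenerate PCA: training submatrix has zero variance",
         call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = scale.)
  loading <- fit$rotation[, 1L]
  if (loading[which.max(abs(loading))] < 0) loading <- -loading
  structure(list(method = "PCA", genes = genes, center = fit$center,
                 scale = if (scale.) fit$scale else NULL,
                 loading = loading),
            class = "baseline_model")
}

#' Project samples onto a fitted PCA activity model
#'
#' @param model A model from [pca_activity_fit()].
#' @param expr Expression matrix to score.
#' @return Named numeric vector of activity scores; scores of the
#'   training samples have zero mean by construction.
#' @export
pca_activity_apply <- function(model, expr) {
  stopifnot(inherits(model, "baseline_model"), model$method == "PCA")
  validate_expression(expr)
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- t(expr[model$genes, , drop = FALSE])
  X <- sweep(X, 2L, model$center)
  if (!is.null(model$scale)) X <- sweep(X, 2L, model$scale, "/")
  drop(X %*% model$loading)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("baseline_model (%s), %d gene(s)\n", x$method,
              length(x$genes)))
  invisible(x)
}
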