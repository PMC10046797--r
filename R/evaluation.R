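#' Repeated stratified cross-validation plan
#'
#' Assigns each sample to one fold per repeat so that per-class counts
#' across the folds of a repeat differ by at most one. The assignment is
#' deterministic given `seed`. Classes with fewer members than folds are
#' spread round-robin (with a warning), leaving some folds without that
#' class.
#'
#' @param labels Phenotype labels (see [phenotype_labels()]).
#' @param k Number of folds, default 10.
#' @param repeats Number of repetitions, default 3 (`k * repeats`
#'   train/test splits in total).
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: `k`, `repeats`, `seed` and
#'   `assignments`, a list (one per repeat) of named fold indices.
#' @export
stratified_cv_split <- function(labels, k = 10L, repeats = 3L, seed = 1L) {
  labels <- as_phenotype_labels(labels)
  if (!is.numeric(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  stopifnot(repeats >= 1L)
  k <- as.integer(k); repeats <- as.integer(repeats)
  small <- table(labels) < k
  if (any(small)) {
    warning("class(es) with fewer members than folds, spread round-robin: ",
            paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  assignments <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      names(fold) <- names(labels)
      for (cl in levels(labels)) {
        ids <- sample(names(labels)[labels == cl])
        offset <- sample.int(k, 1L) - 1L
        fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      }
      fold
    })
  })
  structure(list(k = k, repeats = repeats, seed = seed,
                 assignments = assignments),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d-fold x %d repeat(s) = %d splits, %d samples, seed %s\n",
              x$k, x$repeats, x$k * x$repeats,
              length(x$assignments[[1L]]), format(x$seed)))
  invisible(x)
}

#' Materialise the train/test splits of a cross-validation plan
#'
#' @param plan A [stratified_cv_split()] plan.
#' @return List of `k * repeats` splits, each a list with `repeat_`,
#'   `fold`, `train` and `test` sample-id vectors.
#' @export
cv_splits <- function(plan) {
  stopifnot(inherits(plan, "cv_plan"))
  out <- list()
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignments[[r]]
    for (f in seq_len(plan$k)) {
      test <- names(fold)[fold == f]
      out[[length(out) + 1L]] <-
        list(repeat_ = r, fold = f,
             train = names(fold)[fold != f], test = test)
    }
  }
  out
}

#' Enumerate the per-pathway model solves a plan implies
#'
#' One MILP is trained per pathway and per train/test split; this lists
#' the full schedule (without solving anything), e.g. to size a run.
#'
#' @param gene_sets Named list of gene sets.
#' @param plan A [stratified_cv_split()] plan.
#' @return `data.frame` with columns `pathway_id`, `repeat_`, `fold`; one
#'   row per scheduled solve.
#' @export
milp_schedule <- function(gene_sets, plan) {
  stopifnot(inherits(plan, "cv_plan"), !is.null(names(gene_sets)))
  grid <- expand.grid(fold = seq_len(plan$k),
                      repeat_ = seq_len(plan$repeats),
                      pathway_id = names(gene_sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[, c("pathway_id", "repeat_", "fold")]
}

#' Classification metrics: accuracy and macro precision/recall/F1
#'
#' Per-class precision, recall and F1 are macro-averaged over the classes
#' present in `y_true`; zero-denominator cases contribute 0.
#'
#' @param y_true True class labels.
#' @param y_pred Predicted class labels (same length).
#' @return Named list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(y_true))
  per <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3L))
  list(accuracy = mean(y_true == y_pred),
       precision = mean(per[1L, ]),
       recall = mean(per[2L, ]),
       f1 = mean(per[3L, ]))
}

#' Perturb expression data by within-gene sample permutation
#'
#' Emulates measurement noise by selecting a fraction of genes (without
#' replacement) and independently permuting each selected gene's values
#' across samples. Unselected rows are bit-identical and each gene keeps
#' its exact multiset of values. The number of selected genes is
#' `fraction * n_genes` rounded half away from zero.
#'
#' @param expr Expression matrix (genes x samples).
#' @param fraction Fraction of genes to perturb, in `[0, 1]`.
#' @param seed Integer seed controlling both the gene selection and the
#'   permutations.
#' @return Perturbed expression matrix of identical shape.
#' @export
perturb_expression <- function(expr, fraction, seed = 1L) {
  validate_expression(expr)
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1)
  n_sel <- as.integer(round_half_away(fraction * nrow(expr)))
  if (n_sel == 0L) return(expr)
  with_seed(seed, {
    rows <- sample.int(nrow(expr), n_sel)
    for (i in rows) {
      expr[i, ] <- expr[i, sample.int(ncol(expr))]
    }
    expr
  })
}

#' Minimal external-classifier contract: nearest centroid
#'
#' The evaluation harness trains classifiers on pathway x sample activity
#' matrices through a two-function contract (`fit(activities, labels)`,
#' `predict(model, activities)`). The built-in default is a nearest
#' Euclidean centroid classifier; any classifier honouring the contract
#' (e.g. a random forest wrapper) can be substituted.
#'
#' @return Object of class `dioptra_classifier`.
#' @export
nearest_centroid_classifier <- function() {
  structure(list(
    fit = function(activities, labels) {
      y <- labels_for(labels, colnames(activities))
      ok <- rowSums(is.na(activities)) == 0L
      A <- activities[ok, , drop = FALSE]
      centroids <- vapply(levels(y), function(cl) {
        rowMeans(A[, y == cl, drop = FALSE])
      }, numeric(nrow(A)))
      list(rows = rownames(A), classes = levels(y), centroids = centroids)
    },
    predict = function(model, activities) {
      A <- activities[model$rows, , drop = FALSE]
      d2 <- vapply(seq_along(model$classes), function(j) {
        colSums((A - model$centroids[, j])^2)
      }, numeric(ncol(A)))
      d2 <- matrix(d2, ncol = length(model$classes))
      # which.min takes the first minimum: ties resolve to class order
      model$classes[apply(d2, 1L, which.min)]
    }),
    class = "dioptra_classifier")
}

#' Run a cross-validated pathway-activity experiment
#'
#' For every train/test split of `plan`, fits the chosen activity method
#' on the training fold only, scores both folds, predicts the test-fold
#' classes and computes classification metrics. With `method = "DIOPTRA"`
#' the prediction is model-native (nearest-interval allocation combined
#' by majority vote across pathways); for the baselines (`"MEAN"`,
#' `"PCA"`) test activities are classified by `classifier`.
#'
#' @param expr Full expression matrix.
#' @param gene_sets Named list of gene sets.
#' @param labels Phenotype labels for every sample.
#' @param method `"DIOPTRA"`, `"MEAN"` or `"PCA"`.
#' @param plan A [stratified_cv_split()] plan.
#' @param config [model_config()] for the optimisation method.
#' @param classifier Classifier contract used for the baseline methods;
#'   default [nearest_centroid_classifier()].
#' @param ranking `"test"` (default) or `"train"`: which fold's
#'   allocations feed the individual pathway accuracies used for pathway
#'   ranking. Test-side ranking avoids optimistic bias.
#' @return Object of class `dioptra_experiment` with per-split `metrics`,
#'   their `summary` (mean and standard error), pooled test `predictions`,
#'   `pathway_accuracy` per run, `pathway_ranking`, accumulated absolute
#'   `gene_weights` per pathway, solver `status_counts` and provenance.
#' @export
run_experiment <- function(expr, gene_sets, labels,
                           method = c("DIOPTRA", "MEAN", "PCA"),
                           plan, config = model_config(),
                           classifier = nearest_centroid_classifier(),
                           ranking = c("test", "train")) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  validate_expression(expr)
  labels <- as_phenotype_labels(labels)
  stopifnot(inherits(plan, "cv_plan"))

  members <- lapply(gene_sets, intersect, x = rownames(expr))
  skipped <- names(members)[lengths(members) == 0L]
  if (length(skipped)) {
    warning("skipping pathway(s) with no genes in the matrix: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  members <- members[lengths(members) > 0L]

  splits <- cv_splits(plan)
  metrics <- list(); preds <- list(); pw_acc <- list()
  solutions <- stats::setNames(vector("list", length(members)),
                               names(members))
  status_counts <- c(OPTIMAL = 0L, FEASIBLE = 0L, NO_SOLUTION = 0L)

  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    X_tr <- expr[, sp$train, drop = FALSE]
    X_te <- expr[, sp$test, drop = FALSE]
    y_te <- labels[sp$test]

    if (method == "DIOPTRA") {
      fit <- fit_dioptra(X_tr, members, labels, config)
      for (s in fit) {
        status_counts[s$status] <- status_counts[s$status] + 1L
      }
      tab_te <- allocation_table(fit, X_te)
      pred <- combined_predictions(tab_te)
      y_pred <- stats::setNames(pred$class, pred$sample_id)[sp$test]
      tab_rank <- if (ranking == "test") tab_te
                  else allocation_table(fit, X_tr)
      for (pw in unique(tab_rank$pathway_id)) {
        sub <- tab_rank[tab_rank$pathway_id == pw, , drop = FALSE]
        pw_acc[[length(pw_acc) + 1L]] <- data.frame(
          pathway_id = pw, repeat_ = sp$repeat_, fold = sp$fold,
          accuracy = individual_pathway_accuracy(sub, labels),
          stringsAsFactors = FALSE)
      }
      for (pw in names(fit)) {
        solutions[[pw]] <- c(solutions[[pw]], list(fit[[pw]]))
      }
    } else {
      act <- function(X) {
        t(vapply(names(members), function(pw) {
          if (method == "MEAN") {
            mean_activity(X, members[[pw]])
          } else {
            stop("internal", call. = FALSE)  # replaced below for PCA
          }
        }, numeric(ncol(X))))
      }
      if (method == "MEAN") {
        A_tr <- act(X_tr); A_te <- act(X_te)
      } else {
        models <- lapply(members, pca_activity_fit, expr_train = X_tr)
        A_tr <- t(vapply(models, pca_activity_apply, numeric(ncol(X_tr)),
                         expr = X_tr))
        A_te <- t(vapply(models, pca_activity_apply, numeric(ncol(X_te)),
                         expr = X_te))
      }
      colnames(A_tr) <- sp$train; colnames(A_te) <- sp$test
      model <- classifier$fit(A_tr, labels)
      y_pred <- stats::setNames(classifier$predict(model, A_te), sp$test)
    }

    metrics[[i]] <- data.frame(repeat_ = sp$repeat_, fold = sp$fold,
                               classification_metrics(y_te, y_pred))
    preds[[i]] <- data.frame(repeat_ = sp$repeat_, fold = sp$fold,
                             sample_id = sp$test,
                             truth = as.character(y_te),
                             predicted = as.character(y_pred),
                             stringsAsFactors = FALSE)
  }

  metrics <- do.call(rbind, metrics)
  mcols <- c("accuracy", "precision", "recall", "f1")
  summary <- data.frame(
    metric = mcols,
    mean = vapply(mcols, function(m) mean(metrics[[m]]), numeric(1L)),
    se = vapply(mcols, function(m) {
      stats::sd(metrics[[m]]) / sqrt(nrow(metrics))
    }, numeric(1L)),
    row.names = NULL)
  pw_acc <- if (length(pw_acc)) do.call(rbind, pw_acc) else NULL
  out <- list(method = method, plan = plan, config = config,
              metrics = metrics, summary = summary,
              predictions = do.call(rbind, preds),
              pathway_accuracy = pw_acc,
              pathway_ranking = if (!is.null(pw_acc)) rank_pathways(pw_acc),
              gene_weights = if (method == "DIOPTRA") {
                lapply(Filter(length, solutions), rank_genes)
              },
              solutions = if (method == "DIOPTRA") solutions,
              status_counts = status_counts, skipped = skipped)
  structure(out, class = "dioptra_experiment")
}

#' @export
print.dioptra_experiment <- function(x, ...) {
  cat(sprintf("dioptra_experiment: method %s, %d split(s)\n",
              x$method, nrow(x$metrics)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.4f +/- %.4f (se)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$se[i]))
  }
  if (x$method == "DIOPTRA") {
    cat("  solver statuses:",
        paste(names(x$status_counts), x$status_counts, collapse = ", "),
        "\n")
  }
  invisible(x)
}
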