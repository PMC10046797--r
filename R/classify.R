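#' Violation distance between an activity value and a class interval
#'
#' Zero when the activity lies inside the interval, otherwise the distance
#' to the nearest endpoint: `max(0, LO - pa, pa - UP)`.
#'
#' @param pa Numeric activity value(s).
#' @param interval Length-2 numeric `(LO, UP)` with `LO <= UP`.
#' @return Nonnegative numeric vector the length of `pa`.
#' @export
violation_distance <- function(pa, interval) {
  stopifnot(is.numeric(pa), is.numeric(interval), length(interval) == 2L)
  if (interval[1L] > interval[2L]) {
    stop("invalid interval: LO > UP", call. = FALSE)
  }
  pmax(0, interval[1L] - pa, pa - interval[2L])
}

#' Allocate a sample to its nearest class interval
#'
#' The allocated class minimises the violation distance; ties are broken
#' by the deterministic class sort order (the row order of `intervals`).
#'
#' @param pa Single activity value.
#' @param intervals Matrix with one row per class (rownames are class
#'   labels) and columns `LO`, `UP`, as in a `pathway_solution`.
#' @return List with elements `class` and `distance`.
#' @export
allocate_sample <- function(pa, intervals) {
  stopifnot(length(pa) == 1L)
  d <- allocation_distances(pa, intervals)[1L, ]
  i <- which.min(d)
  list(class = rownames(intervals)[i], distance = unname(d[i]))
}

# distances of each activity (rows) to each class interval (cols)
allocation_distances <- function(pa, intervals) {
  if (!is.matrix(intervals) || nrow(intervals) < 1L ||
      is.null(rownames(intervals))) {
    stop("intervals must be a non-empty matrix with class rownames",
         call. = FALSE)
  }
  if (any(intervals[, 1L] > intervals[, 2L])) {
    stop("invalid interval: LO > UP", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    violation_distance(pa, intervals[i, ])
  }, numeric(length(pa)))
  out <- matrix(out, nrow = length(pa),
                dimnames = list(names(pa), rownames(intervals)))
  out
}

#' Per-pathway allocation table for a set of samples
#'
#' Scores `expr` with each solved pathway's weights and allocates every
#' sample to its nearest class interval. Pathways whose solve produced no
#' solution have no intervals and are excluded.
#'
#' @param fit A `dioptra_fit` or named list of `pathway_solution`s.
#' @param expr Expression matrix of the samples to allocate (training or
#'   unseen).
#' @return `data.frame` with columns `pathway_id`, `sample_id`, `class`,
#'   `distance`.
#' @export
allocation_table <- function(fit, expr) {
  validate_expression(expr)
  rows <- lapply(names(fit), function(pw) {
    sol <- fit[[pw]]
    if (is.null(sol$intervals)) return(NULL)
    pa <- compute_pathway_activity(sol$signed_weights, expr)
    d <- allocation_distances(pa, sol$intervals)
    i <- apply(d, 1L, which.min)
    data.frame(pathway_id = pw, sample_id = colnames(expr),
               class = rownames(sol$intervals)[i],
               distance = d[cbind(seq_along(i), i)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(), sample_id = character(),
                      class = character(), distance = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Individual pathway prediction accuracy
#'
#' Fraction of samples allocated to their labelled class.
#'
#' @param allocations Named character vector of allocated classes (names
#'   are sample ids), or an [allocation_table()] slice for one pathway.
#' @param labels Phenotype labels.
#' @return Accuracy in `[0, 1]`.
#' @export
individual_pathway_accuracy <- function(allocations, labels) {
  if (is.data.frame(allocations)) {
    x <- allocations$class
    names(x) <- allocations$sample_id
    allocations <- x
  }
  if (length(allocations) == 0L) {
    stop("no allocations provided", call. = FALSE)
  }
  y <- labels_for(labels, names(allocations))
  mean(as.character(y) == as.character(allocations))
}

#' Combined (majority-vote) prediction for one sample
#'
#' Each solved pathway votes with its allocation; the per-class vote
#' fraction is the share of pathways allocating the sample to that class,
#' and the predicted class is the one with the highest fraction. Vote
#' ties are broken by the smaller summed violation distance across the
#' tied pathways' allocations, then by class sort order.
#'
#' @param table An [allocation_table()].
#' @param sample_id Sample to predict.
#' @return List with `class` and the named vector `fractions`.
#' @export
combined_prediction <- function(table, sample_id) {
  rows <- table[table$sample_id == sample_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no pathway allocations for sample ", sample_id, call. = FALSE)
  }
  cls <- sort(unique(table$class))
  votes <- table(factor(rows$class, levels = cls))
  fractions <- as.numeric(votes) / nrow(rows)
  names(fractions) <- cls
  top <- which(fractions == max(fractions))
  if (length(top) > 1L) {
    dist_sum <- vapply(cls[top], function(cc) {
      sum(rows$distance[rows$class == cc])
    }, numeric(1L))
    top <- top[order(dist_sum)]          # stable: class order breaks ties
  }
  list(class = cls[top[1L]], fractions = fractions)
}

#' Combined predictions for every sample in an allocation table
#'
#' @param table An [allocation_table()].
#' @return `data.frame` with columns `sample_id` and `class`, one row per
#'   sample, plus vote-fraction columns prefixed `frac.`.
#' @export
combined_predictions <- function(table) {
  ids <- unique(table$sample_id)
  res <- lapply(ids, function(s) combined_prediction(table, s))
  fr <- do.call(rbind, lapply(res, `[[`, "fractions"))
  out <- data.frame(sample_id = ids,
                    class = vapply(res, `[[`, character(1L), "class"),
                    stringsAsFactors = FALSE)
  colnames(fr) <- paste0("frac.", colnames(fr))
  cbind(out, fr, row.names = NULL)
}

#' Rank pathways by mean prediction accuracy
#'
#' @param accuracies `data.frame` with columns `pathway_id` and
#'   `accuracy` (one row per pathway per run).
#' @return `data.frame` ordered by descending mean accuracy (ties by
#'   pathway id), with columns `rank`, `pathway_id`, `mean_accuracy`,
#'   `n_runs`.
#' @export
rank_pathways <- function(accuracies) {
  stopifnot(is.data.frame(accuracies),
            all(c("pathway_id", "accuracy") %in% colnames(accuracies)))
  agg <- stats::aggregate(accuracy ~ pathway_id, accuracies,
                          function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(pathway_id = agg$pathway_id,
                    mean_accuracy = agg$accuracy[, "mean"],
                    n_runs = as.integer(agg$accuracy[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_accuracy, out$pathway_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Rank a pathway's genes by accumulated absolute weight
#'
#' Sums `|rp_m - rn_m|` over repeated model trainings of the same
#' pathway. Because the absolute weights of each training sum to one, the
#' accumulated weights over `n` runs total `n`.
#'
#' @param solutions List of `pathway_solution`s for one pathway (e.g. one
#'   per cross-validation training fold).
#' @return Named numeric vector of accumulated absolute weights, sorted
#'   decreasingly (ties by gene id).
#' @export
rank_genes <- function(solutions) {
  solutions <- Filter(function(s) !is.null(s$signed_weights), solutions)
  if (!length(solutions)) return(numeric(0))
  genes <- sort(unique(unlist(lapply(solutions, `[[`, "gene_ids"))))
  acc <- structure(numeric(length(genes)), names = genes)
  for (s in solutions) {
    w <- abs(s$signed_weights)
    acc[names(w)] <- acc[names(w)] + w
  }
  acc[order(-acc, names(acc))]
}
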