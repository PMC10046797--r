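#' Read a gene expression matrix from delimited text
#'
#' Expression input follows the common transcriptomics layout: genes in
#' rows, samples in columns, a header row of sample identifiers and the
#' first column holding gene identifiers. Values must be numeric,
#' nonnegative and complete (`NA`/`NaN` are rejected rather than treated as
#' zero); zero is the only missingness sentinel, as in FPKM-like data.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @seealso [write_expression()], [filter_genes()]
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  gene_ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  mat <- suppressWarnings(
    vapply(vals, as.numeric, numeric(nrow(df)))
  )
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(gene_ids, colnames(vals)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
  }
  validate_expression(mat, what = basename(path))
  mat
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]; `read_expression(write_expression(x))`
#' reproduces `x` exactly for finite decimal inputs.
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param delimiter Field separator.
#' @param id_column Name used for the gene id column header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t",
                             id_column = "gene_id") {
  validate_expression(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-delimited fields
#' `name`, `description`, then one or more member gene identifiers.
#' Duplicate gene ids within one set are collapsed; the total number of
#' collapsed duplicates is reported with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set, in file order)
#'   with a `"description"` attribute carrying the per-set description.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    n_dup <- n_dup + sum(duplicated(genes))
    ids[[i]] <- fields[[1L]]
    desc[[i]] <- fields[[2L]]
    sets[[i]] <- unique(genes)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  names(desc) <- ids
  if (n_dup > 0L) {
    warning(sprintf("collapsed %d duplicate gene id(s) within sets", n_dup),
            call. = FALSE)
  }
  structure(sets, description = desc)
}

#' Write a gene-set collection in GMT format
#'
#' @param gene_sets Named list of character vectors; an optional
#'   `"description"` attribute supplies the second GMT column (defaults to
#'   the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  desc <- attr(gene_sets, "description") %||% names(gene_sets)
  if (is.null(names(desc))) names(desc) <- names(gene_sets)
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, desc[[id]] %||% id, gene_sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct phenotype labels with a deterministic class order
#'
#' Class levels are sorted with [sort()] so the class order (used for
#' constraint generation and all tie-breaks) is reproducible and recorded
#' in the factor levels.
#'
#' @param labels Named character vector (names are sample ids) or a
#'   data.frame whose first two columns are sample id and class label.
#' @return Named factor, one entry per sample, levels in sorted order.
#' @export
phenotype_labels <- function(labels) {
  if (is.data.frame(labels)) {
    x <- as.character(labels[[2L]])
    names(x) <- as.character(labels[[1L]])
    labels <- x
  }
  if (is.factor(labels)) {
    x <- as.character(labels)
    names(x) <- names(labels)
    labels <- x
  }
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop("labels must be named by sample id", call. = FALSE)
  }
  if (anyDuplicated(names(labels))) {
    stop("duplicate sample id(s) in labels: ",
         paste(unique(names(labels)[duplicated(names(labels))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(labels)) stop("missing class label(s)", call. = FALSE)
  factor(labels, levels = sort(unique(unname(labels))))
}

#' Read a sample phenotype label table
#'
#' Two-column delimited text: sample id, class label.
#'
#' @param path Path to the file.
#' @param delimiter Field separator.
#' @param header Whether the file has a header row.
#' @return Named factor as produced by [phenotype_labels()].
#' @export
read_labels <- function(path, delimiter = "\t", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = header,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("label table needs two columns", call. = FALSE)
  phenotype_labels(df[, 1:2])
}

#' Write a sample phenotype label table
#'
#' @param labels Named factor or character vector of class labels.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  labels <- as_phenotype_labels(labels)
  df <- data.frame(sample_id = names(labels),
                   class_label = as.character(labels))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Remove genes with a high fraction of zero expression values
#'
#' Genes whose fraction of zeros across the cohort exceeds
#' `max_zero_fraction` (strictly greater than) are removed; genes at
#' exactly the threshold are retained. Sample set and the relative order
#' of surviving genes are unchanged, and the filter is idempotent.
#'
#' @param expr Expression matrix (genes x samples).
#' @param max_zero_fraction Maximum tolerated zero fraction, default 0.30.
#' @return The filtered expression matrix.
#' @export
filter_genes <- function(expr, max_zero_fraction = 0.30) {
  validate_expression(expr)
  stopifnot(is.numeric(max_zero_fraction), length(max_zero_fraction) == 1L,
            max_zero_fraction >= 0, max_zero_fraction <= 1)
  zero_frac <- rowMeans(expr == 0)
  keep <- zero_frac <= max_zero_fraction
  if (!any(keep)) {
    stop(sprintf("all %d genes exceed the %.0f%% zero-fraction threshold",
                 nrow(expr), 100 * max_zero_fraction), call. = FALSE)
  }
  expr[keep, , drop = FALSE]
}
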