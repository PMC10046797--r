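# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps seeded operations (CV plans,
# perturbation, simulation) from disturbing the global RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate an expression matrix: numeric genes x samples matrix with unique
# dimnames, finite nonnegative values. Returns the matrix invisibly.
validate_expression <- function(expr, what = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  gn <- rownames(expr)
  sn <- colnames(expr)
  if (is.null(gn) || is.null(sn)) {
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(gn)) {
    stop("duplicate gene id(s): ",
         paste(unique(gn[duplicated(gn)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sn)) {
    stop("duplicate sample id(s): ",
         paste(unique(sn[duplicated(sn)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(expr) || any(!is.finite(expr))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  if (any(expr < 0)) {
    stop(what, " contains negative expression values", call. = FALSE)
  }
  invisible(expr)
}

# Coerce labels to a named factor with a deterministic (sorted) class order.
as_phenotype_labels <- function(labels) {
  if (is.factor(labels) && !is.null(names(labels))) {
    if (anyDuplicated(names(labels))) {
      stop("duplicate sample id(s) in labels", call. = FALSE)
    }
    return(labels)
  }
  phenotype_labels(labels)
}

# labels restricted (and level-dropped) to the given samples, in that order
labels_for <- function(labels, sample_ids) {
  labels <- as_phenotype_labels(labels)
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing)) {
    stop("unlabelled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  droplevels(labels[sample_ids])
}
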