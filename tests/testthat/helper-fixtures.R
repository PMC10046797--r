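# Small in-code fixtures shared across tests.

# genes x samples matrix with auto-generated ids
expr_fixture <- function(values, n_genes, n_samples,
                         genes = paste0("g", seq_len(n_genes)),
                         samples = paste0("s", seq_len(n_samples))) {
  matrix(values, nrow = n_genes, ncol = n_samples,
         dimnames = list(genes, samples))
}

# labels for samples s1, s2, ... in order
labels_fixture <- function(classes, samples = paste0("s", seq_along(classes))) {
  phenotype_labels(stats::setNames(classes, samples))
}

# seeded random small instance within the enumeration-oracle guard
random_small_instance <- function(seed, max_genes = 4L, max_classes = 3L,
                                  max_samples = 12L) {
  set.seed(seed)
  M <- sample.int(max_genes, 1L)
  C <- sample(2:max_classes, 1L)
  S <- sample(6:max_samples, 1L)
  expr <- expr_fixture(round(runif(M * S, 0, 10), 2), M, S)
  y <- sample(LETTERS[seq_len(C)], S, replace = TRUE)
  while (length(unique(y)) < 2L) y <- sample(LETTERS[seq_len(C)], S, TRUE)
  list(expr = expr, labels = labels_fixture(y))
}

# recompute the objective from extracted activities and intervals
recomputed_objective <- function(sol, labels) {
  y <- as.character(labels[names(sol$activities)])
  sum(pmax(0,
           sol$intervals[y, "LO"] - sol$activities,
           sol$activities - sol$intervals[y, "UP"]))
}

# check all pathway_solution invariants at the given tolerance
expect_solution_invariants <- function(sol, labels, tol = 1e-6) {
  expect_equal(sum(sol$rp + sol$rn), 1, tolerance = tol)
  expect_true(all(pmin(sol$rp, sol$rn) <= tol))
  eps <- sol$epsilon
  C <- nrow(sol$intervals)
  expect_true(all(sol$intervals[, "UP"] - sol$intervals[, "LO"] >=
                    eps - tol))
  if (C > 1L) {
    for (k in seq_len(C - 1L)) {
      for (cc in (k + 1L):C) {
        sep_up <- sol$intervals[cc, "LO"] - sol$intervals[k, "UP"]
        sep_dn <- sol$intervals[k, "LO"] - sol$intervals[cc, "UP"]
        expect_true(max(sep_up, sep_dn) >= eps - tol)
      }
    }
  }
  expect_equal(sol$objective, recomputed_objective(sol, labels),
               tolerance = tol)
}
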