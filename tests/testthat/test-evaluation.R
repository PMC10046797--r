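test_that("stratified folds balance class counts to within one", {
  classes <- rep(c("c1", "c2", "c3", "c4"), times = c(40, 30, 20, 10))
  labels <- labels_fixture(classes,
                           samples = sprintf("s%03d", seq_along(classes)))
  plan <- stratified_cv_split(labels, k = 10, repeats = 3, seed = 7)
  for (r in 1:3) {
    fold <- plan$assignments[[r]]
    # folds partition the samples
    expect_setequal(names(fold), names(labels))
    counts <- table(labels[names(fold)], fold)
    expect_identical(dim(counts), c(4L, 10L))
    expect_true(all(apply(counts, 1, function(v) diff(range(v))) <= 1))
    # exact divisibility here: every fold has 4/3/2/1 per class
    expect_true(all(counts == matrix(c(4, 3, 2, 1), 4, 10)))
  }
  expect_length(cv_splits(plan), 30)
  # deterministic given the seed
  plan2 <- stratified_cv_split(labels, k = 10, repeats = 3, seed = 7)
  expect_identical(plan, plan2)
  expect_error(stratified_cv_split(labels, k = 1), "k must be")
  tiny <- labels_fixture(c(rep("A", 12), rep("B", 2)))
  expect_warning(stratified_cv_split(tiny, k = 5, seed = 1), "round-robin")
})

test_that("train and test partition every split", {
  labels <- labels_fixture(rep(c("A", "B"), 10))
  plan <- stratified_cv_split(labels, k = 5, repeats = 2, seed = 3)
  for (sp in cv_splits(plan)) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), names(labels))
  }
})

test_that("classification metrics reproduce the hand-worked confusion table", {
  m <- classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 5 / 6, tolerance = 1e-9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 11 / 15, tolerance = 1e-9)

  perfect <- classification_metrics(c("A", "B"), c("A", "B"))
  expect_true(all(unlist(perfect) == 1))
  flipped <- classification_metrics(c("A", "B"), c("B", "A"))
  expect_equal(flipped$accuracy, 0)
  expect_error(classification_metrics("A", c("A", "B")), "length")
  # classes absent from y_true do not enter the macro average
  m2 <- classification_metrics(c("A", "A"), c("A", "C"))
  expect_equal(m2$precision, 1)   # only class A averaged, P_A = 1
  expect_equal(m2$recall, 0.5)
})

test_that("perturbation preserves per-gene multisets and selection counts", {
  set.seed(31)
  expr <- expr_fixture(round(exp(rnorm(100 * 12)), 3), 100, 12)
  expect_identical(perturb_expression(expr, 0, seed = 5), expr)

  out <- perturb_expression(expr, 0.5, seed = 5)
  changed <- rowSums(out != expr) > 0
  expect_identical(dim(out), dim(expr))
  for (i in seq_len(nrow(expr))) {
    expect_identical(sort(unname(out[i, ])), sort(unname(expr[i, ])))
  }
  # exactly 50 rows selected; unselected rows bit-identical
  expect_lte(sum(changed), 50)
  expect_identical(out[!changed, ], expr[!changed, ])

  all_p <- perturb_expression(expr, 1, seed = 2)
  for (i in seq_len(nrow(expr))) {
    expect_identical(sort(unname(all_p[i, ])), sort(unname(expr[i, ])))
  }
  # deterministic given seed
  expect_identical(perturb_expression(expr, 0.3, seed = 9),
                   perturb_expression(expr, 0.3, seed = 9))
})

test_that("perturbed gene count rounds half away from zero", {
  expr <- expr_fixture(matrix(runif(10 * 4), 10), 10, 4)
  # 0.25 * 10 = 2.5 -> 3 genes permuted (seed chosen arbitrarily)
  out <- perturb_expression(expr, 0.25, seed = 1)
  expect_lte(sum(rowSums(out != expr) > 0), 3)
  expect_equal(dioptra:::round_half_away(2.5), 3)
  expect_equal(dioptra:::round_half_away(-2.5), -3)
})

test_that("the milp schedule enumerates pathway x split combinations", {
  labels <- labels_fixture(rep(c("A", "B"), 10))
  plan <- stratified_cv_split(labels, k = 5, repeats = 2, seed = 1)
  sets <- setNames(replicate(7, "g1", simplify = FALSE), paste0("pw", 1:7))
  sched <- milp_schedule(sets, plan)
  expect_identical(nrow(sched), 70L)
  expect_identical(colnames(sched), c("pathway_id", "repeat_", "fold"))
  expect_identical(anyDuplicated(sched), 0L)
})

test_that("experiments are deterministic and blind to test folds", {
  spec <- simulation_spec(n_classes = 2, n_samples_per_class = 8,
                          n_pathways = 2, genes_per_pathway = 3,
                          effect_size = 1.5, noise_sd = 0.15, seed = 13)
  ds <- generate_dataset(spec)
  plan <- stratified_cv_split(ds$labels, k = 4, repeats = 1, seed = 2)
  ex1 <- run_experiment(ds$expression, ds$gene_sets, ds$labels, "DIOPTRA",
                        plan)
  ex2 <- run_experiment(ds$expression, ds$gene_sets, ds$labels, "DIOPTRA",
                        plan)
  expect_identical(ex1$metrics, ex2$metrics)
  expect_identical(ex1$gene_weights, ex2$gene_weights)

  # replacing test-fold expression leaves fitted weights untouched
  sp <- cv_splits(plan)[[1]]
  tampered <- ds$expression
  tampered[, sp$test] <- 999
  f_orig <- fit_dioptra(ds$expression[, sp$train], ds$gene_sets, ds$labels)
  f_tamp <- fit_dioptra(tampered[, sp$train], ds$gene_sets, ds$labels)
  expect_identical(lapply(f_orig, `[[`, "signed_weights"),
                   lapply(f_tamp, `[[`, "signed_weights"))
})

test_that("baseline experiments run under the classifier contract", {
  spec <- simulation_spec(n_classes = 2, n_samples_per_class = 10,
                          n_pathways = 3, genes_per_pathway = 4,
                          effect_size = 1.5, noise_sd = 0.15, seed = 17)
  ds <- generate_dataset(spec)
  plan <- stratified_cv_split(ds$labels, k = 4, repeats = 1, seed = 6)
  for (method in c("MEAN", "PCA")) {
    ex <- run_experiment(ds$expression, ds$gene_sets, ds$labels, method,
                         plan)
    expect_true(all(ex$metrics$accuracy >= 0 & ex$metrics$accuracy <= 1))
    # aggregated mean lies within the per-split range
    expect_gte(ex$summary$mean[1], min(ex$metrics$accuracy))
    expect_lte(ex$summary$mean[1], max(ex$metrics$accuracy))
  }
})

test_that("constant expression degrades to the plurality tie-break class", {
  expr <- expr_fixture(5, 4, 12)
  labels <- labels_fixture(rep(c("A", "B", "C"), each = 4))
  plan <- stratified_cv_split(labels, k = 4, repeats = 1, seed = 11)
  sets <- list(pw1 = c("g1", "g2"), pw2 = c("g3", "g4"))
  ex <- run_experiment(expr, sets, labels, "MEAN", plan)
  # all distances tie; predictions collapse to the first class in order,
  # so accuracy equals that class's share of each (stratified) test fold
  expect_true(all(ex$predictions$predicted == "A"))
  expect_equal(ex$summary$mean[ex$summary$metric == "accuracy"], 1 / 3,
               tolerance = 1e-9)
})
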