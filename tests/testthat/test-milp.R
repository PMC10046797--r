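test_that("model_config validates its constants", {
  cfg <- model_config()
  expect_equal(cfg$epsilon, 1e-3)
  expect_equal(cfg$time_limit_s, 200)
  expect_equal(cfg$relative_gap_target, 0)
  expect_error(model_config(epsilon = 0))
  expect_error(model_config(big_M = 1e-3), "big_M")
  expect_error(model_config(time_limit_s = -1))
})

test_that("resolve_big_M follows the documented formula", {
  expr <- expr_fixture(c(1, 10, 3, 4), 2, 2)
  expect_equal(resolve_big_M(expr, 0.001), 20.003)
  expect_equal(resolve_big_M(expr_fixture(0, 2, 2), 0.001), 0.003)
  # dominant term scales with the data
  expect_equal(resolve_big_M(10 * expr, 0.001), 200.003)
})

test_that("compute_pathway_activity is the weighted sum of expression", {
  expr <- expr_fixture(c(4, 2, 6, 8), 2, 2)
  expect_equal(compute_pathway_activity(c(g1 = 1), expr),
               c(s1 = 4, s2 = 6))
  expect_equal(compute_pathway_activity(c(g1 = 0.5, g2 = -0.5), expr),
               c(s1 = 1, s2 = -1))
  expect_equal(compute_pathway_activity(c(g1 = 0, g2 = 0), expr),
               c(s1 = 0, s2 = 0))
  expect_error(compute_pathway_activity(c(gX = 1), expr), "gX")
})

test_that("a perfectly separable one-gene instance solves to zero", {
  expr <- expr_fixture(c(1, 2, 8, 9), 1, 4)
  labels <- labels_fixture(c("A", "A", "B", "B"))
  sol <- solve_dioptra(expr, labels)
  expect_identical(sol$status, "OPTIMAL")
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_equal(abs(sum(sol$signed_weights)), 1, tolerance = 1e-6)
  expect_solution_invariants(sol, labels)
  # each class interval encloses its own samples
  expect_true(all(sol$violations < 1e-9))
})

test_that("the interleaved one-gene instance costs 5 + epsilon", {
  expr <- expr_fixture(c(0, 10, 5), 1, 3)
  labels <- labels_fixture(c("A", "A", "B"))
  sol <- solve_dioptra(expr, labels)
  expect_identical(sol$status, "OPTIMAL")
  expect_equal(sol$objective, 5.001, tolerance = 1e-6)
  expect_solution_invariants(sol, labels)
})

test_that("single-class instances are trivially satisfied", {
  expr <- expr_fixture(c(3, 1, 4, 1, 5, 9), 2, 3)
  labels <- labels_fixture(c("A", "A", "A"))
  sol <- solve_dioptra(expr, labels)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_true(all(sol$violations < 1e-9))
  expect_solution_invariants(sol, labels)
})

test_that("solution invariants hold on random instances", {
  for (seed in 1:6) {
    inst <- random_small_instance(seed, max_genes = 4L)
    sol <- solve_dioptra(inst$expr, inst$labels)
    expect_identical(sol$status, "OPTIMAL")
    expect_solution_invariants(sol, inst$labels)
  }
})

test_that("adding a gene never increases the optimal objective", {
  for (seed in 11:14) {
    inst <- random_small_instance(seed, max_genes = 3L)
    base <- solve_dioptra(inst$expr, inst$labels)$objective
    set.seed(seed + 100)
    extra <- rbind(inst$expr,
                   gX = round(runif(ncol(inst$expr), 0, 10), 2))
    grown <- solve_dioptra(extra, inst$labels)$objective
    expect_lte(grown, base + 1e-6)
  }
})

test_that("objective is invariant to sample order and class relabelling", {
  inst <- random_small_instance(5)
  base <- solve_dioptra(inst$expr, inst$labels)$objective
  set.seed(1)
  perm <- sample(ncol(inst$expr))
  sol_p <- solve_dioptra(inst$expr[, perm, drop = FALSE], inst$labels)
  expect_equal(sol_p$objective, base, tolerance = 1e-6)
  # consistent renaming of the classes
  renamed <- setNames(paste0("Z", as.character(inst$labels)),
                      names(inst$labels))
  sol_r <- solve_dioptra(inst$expr, phenotype_labels(renamed))
  expect_equal(sol_r$objective, base, tolerance = 1e-6)
})

test_that("separable synthetic single-gene classes certify objective zero", {
  # class ranges on the informative gene are disjoint with gaps >> epsilon
  expr <- expr_fixture(c(1, 1.5, 2, 6, 7, 8, 20, 22, 24), 1, 9)
  labels <- labels_fixture(rep(c("A", "B", "C"), each = 3))
  sol <- solve_dioptra(expr, labels)
  expect_equal(sol$objective, 0, tolerance = 1e-9)
})

test_that("unlabelled samples and empty matrices are rejected", {
  expr <- expr_fixture(1:4, 1, 4)
  expect_error(solve_dioptra(expr, labels_fixture(c("A", "B"))),
               "unlabelled")
  expect_error(solve_dioptra(expr[0, , drop = FALSE],
                             labels_fixture(rep("A", 4))))
})

test_that("fit_dioptra skips pathways without genes and names solutions", {
  expr <- expr_fixture(c(1, 2, 2, 3, 8, 9, 9, 10), 2, 4)
  labels <- labels_fixture(c("A", "A", "B", "B"))
  sets <- list(pw1 = c("g1", "g2"), pw2 = "g1", missing = "gZ")
  expect_warning(fit <- fit_dioptra(expr, sets, labels), "missing")
  expect_identical(names(fit), c("pw1", "pw2"))
  expect_identical(attr(fit, "skipped"), "missing")
  expect_equal(fit$pw2$objective, 0, tolerance = 1e-9)
  prof <- activity_profile(fit, expr)
  expect_identical(dim(prof), c(2L, 4L))
  expect_equal(prof["pw2", ],
               compute_pathway_activity(fit$pw2$signed_weights, expr))
})
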