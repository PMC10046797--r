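test_that("violation distance is zero inside and linear outside", {
  expect_equal(violation_distance(6, c(5, 7)), 0)
  expect_equal(violation_distance(3, c(5, 7)), 2)
  expect_equal(violation_distance(9, c(5, 7)), 2)
  expect_equal(violation_distance(c(3, 6, 9), c(5, 7)), c(2, 0, 2))
  expect_error(violation_distance(1, c(7, 5)), "LO > UP")
})

test_that("samples are allocated to the nearest class interval", {
  iv <- rbind(A = c(1, 2), B = c(8, 9))
  colnames(iv) <- c("LO", "UP")
  expect_equal(allocate_sample(8.5, iv), list(class = "B", distance = 0))
  expect_equal(allocate_sample(7.5, iv), list(class = "B", distance = 0.5))
  # equidistant: first class in sort order wins
  expect_equal(allocate_sample(5, iv), list(class = "A", distance = 3))
  expect_error(allocate_sample(1, iv[0, , drop = FALSE]), "non-empty")
})

test_that("individual pathway accuracy is the fraction allocated correctly", {
  labels <- labels_fixture(c("A", "A", "B", "B"))
  expect_equal(individual_pathway_accuracy(
    setNames(c("A", "A", "B", "B"), paste0("s", 1:4)), labels), 1)
  expect_equal(individual_pathway_accuracy(
    setNames(c("A", "B", "B", "B"), paste0("s", 1:4)), labels), 0.75)
  expect_equal(individual_pathway_accuracy(
    setNames(c("B", "B", "A", "A"), paste0("s", 1:4)), labels), 0)
  expect_error(individual_pathway_accuracy(character(0), labels), "no allocations")
})

test_that("combined prediction takes the plurality class over pathways", {
  tab <- data.frame(
    pathway_id = paste0("pw", 1:10),
    sample_id = "s1",
    class = rep(c("c1", "c2", "c3", "c4"), times = c(3, 4, 2, 1)),
    distance = 0)
  res <- combined_prediction(tab, "s1")
  expect_identical(res$class, "c2")
  expect_equal(res$fractions,
               c(c1 = 0.3, c2 = 0.4, c3 = 0.2, c4 = 0.1))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)

  # a single pathway dictates the prediction
  one <- tab[1, , drop = FALSE]
  expect_identical(combined_prediction(one, "s1")$class, tab$class[1])
  expect_error(combined_prediction(tab, "s99"), "s99")
})

test_that("vote ties break by smaller summed violation distance", {
  tab <- data.frame(
    pathway_id = paste0("pw", 1:4),
    sample_id = "s1",
    class = c("A", "A", "B", "B"),
    distance = c(1.7, 1.7, 0.6, 0.6))
  expect_identical(combined_prediction(tab, "s1")$class, "B")
  # equal distances too: class sort order
  tab$distance <- 1
  expect_identical(combined_prediction(tab, "s1")$class, "A")
})

test_that("combined prediction is invariant to pathway row order", {
  set.seed(8)
  tab <- data.frame(
    pathway_id = rep(paste0("pw", 1:7), each = 2),
    sample_id = rep(c("s1", "s2"), 7),
    class = sample(c("A", "B", "C"), 14, replace = TRUE),
    distance = round(runif(14), 3))
  base <- combined_predictions(tab)
  shuf <- combined_predictions(tab[sample(nrow(tab)), ])
  expect_equal(base[order(base$sample_id), ],
               shuf[order(shuf$sample_id), ], ignore_attr = TRUE)
})

test_that("pathway ranking orders by mean accuracy with id tie-break", {
  acc <- data.frame(pathway_id = c("pwA", "pwA", "pwB"),
                    accuracy = c(0.8, 0.6, 0.9))
  rk <- rank_pathways(acc)
  expect_identical(rk$pathway_id, c("pwB", "pwA"))
  expect_equal(rk$mean_accuracy, c(0.9, 0.7))
  expect_identical(rk$n_runs, c(1L, 2L))

  tie <- data.frame(pathway_id = c("pwZ", "pwA"), accuracy = c(0.5, 0.5))
  expect_identical(rank_pathways(tie)$pathway_id, c("pwA", "pwZ"))
  single <- rank_pathways(data.frame(pathway_id = "pw1", accuracy = 1))
  expect_identical(nrow(single), 1L)
})

test_that("gene ranking accumulates absolute weights across runs", {
  mk <- function(w) {
    structure(list(gene_ids = names(w), signed_weights = w,
                   rp = pmax(w, 0), rn = pmax(-w, 0)),
              class = "pathway_solution")
  }
  runs <- list(mk(c(g1 = 0.6, g2 = 0.4)), mk(c(g1 = -0.4, g2 = 0.6)))
  acc <- rank_genes(runs)
  expect_equal(acc, c(g1 = 1.0, g2 = 1.0)[names(acc)])
  # total over genes equals the number of runs
  expect_equal(sum(acc), 2, tolerance = 1e-6)

  runs2 <- list(mk(c(g1 = 1, g2 = 0)), mk(c(g1 = 1, g2 = 0)))
  acc2 <- rank_genes(runs2)
  expect_identical(names(acc2)[1], "g1")
  expect_equal(unname(acc2["g2"]), 0)
})
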