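test_that("embedded mean curves honour their class geometry", {
  set.seed(51)
  flat <- mean_curve("nondynamic", 7, baseline = 120)
  expect_equal(max(abs(diff(log2(flat)))), 0)

  mono <- mean_curve("monotonic", 7, effect = 1, baseline = 100, direction = "up")
  expect_equal(mono[7], 200, tolerance = 1e-9)
  expect_equal(mono[1], 100)
  expect_true(all(diff(mono) > 0))

  for (i in 1:20) {
    ob <- mean_curve("one_break", 7, effect = c(1, 2), baseline = 100)
    l2 <- log2(ob / 100)
    s <- sign(diff(l2))
    expect_equal(sum(diff(s[s != 0]) != 0), 1)   # exactly one reversal
  }
  expect_error(mean_curve("three_break", 4), "at least 5 timepoints")
})

test_that("multi-break anchors stay clear of baseline", {
  set.seed(53)
  for (i in 1:30) {
    tb <- mean_curve("three_break", 9, effect = c(0.5, 2), baseline = 100)
    anchors <- attr(tb, "log2_anchors")
    expect_true(all(abs(anchors[-1]) >= 0.25 - 1e-9))
  }
})

test_that("NB noise is reproducible and matches the moment relation", {
  set.seed(55)
  x1 <- add_nb_noise(c(100, 200), 0.1, n_replicates = 4)
  set.seed(55)
  x2 <- add_nb_noise(c(100, 200), 0.1, n_replicates = 4)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(2L, 4L))

  set.seed(56)
  draws <- add_nb_noise(rep(100, 1), 0.2, n_replicates = 10000)
  v <- var(as.numeric(draws)); expected <- 100 + 0.2 * 100^2
  expect_lt(abs(v - expected) / expected, 0.10)

  # Poisson limit: replicate mean close to the mean at vanishing dispersion
  set.seed(57)
  pl <- add_nb_noise(rep(1000, 1), 1e-13, n_replicates = 100)
  expect_lt(abs(mean(pl) - 1000), 5 * sqrt(1000 / 100))
})

test_that("class apportionment is exact under largest-remainder rounding", {
  sim <- simulate_time_course(n_genes = 1000, n_timepoints = 5, seed = 2)
  expect_equal(nrow(sim$truth), 1000)
  expect_equal(sum(sim$truth$class == "nondynamic"), 900)
  expect_equal(as.integer(table(sim$truth$class)[c("monotonic", "one_break")]),
               c(25L, 25L))
  expect_equal(sim$truth$truth_dynamic, sim$truth$class != "nondynamic")

  per_class <- simulate_time_course(
    n_genes = 200, n_timepoints = 5, seed = 3,
    fractions = c(nondynamic = 0.1, monotonic = 0.9, one_break = 0,
                  two_break = 0, three_break = 0))
  expect_equal(sum(per_class$truth$class == "monotonic"), 180)
})

test_that("monotonic endpoint effects live in the configured range", {
  sim <- simulate_time_course(n_genes = 400, n_timepoints = 5, seed = 4,
                              noiseless = TRUE)
  mono <- sim$truth$gene_id[sim$truth$class == "monotonic"]
  for (g in mono) {
    y <- sim$expt$counts[g, ]
    m0 <- mean(y[sim$expt$metadata$time == 0])
    m4 <- mean(y[sim$expt$metadata$time == 4])
    d <- abs(log2(m4 / m0))
    expect_gte(d, 0.5 - 0.05)   # rounding of small means
    expect_lte(d, 2 + 0.05)
  }
})

test_that("generation is reproducible and time layout is even", {
  s1 <- simulate_time_course(n_genes = 50, n_timepoints = 5, seed = 6)
  s2 <- simulate_time_course(n_genes = 50, n_timepoints = 5, seed = 6)
  expect_identical(s1$expt$counts, s2$expt$counts)
  expect_equal(sort(unique(s1$expt$metadata$time)), 0:4)
  expect_equal(as.integer(table(s1$expt$metadata$time)), rep(3L, 5))
})

test_that("AUC matches pair-counting and an independent implementation", {
  set.seed(61)
  truth <- rep(c(TRUE, FALSE), c(20, 30))
  scores <- rnorm(50) + 1.5 * truth
  auc <- score_auc(scores, truth)
  # O(n^2) pair enumeration oracle with half-credit ties
  pairs <- 0
  for (i in which(truth)) for (j in which(!truth)) {
    pairs <- pairs + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  expect_equal(auc, pairs / (20 * 30), tolerance = 1e-12)

  skip_if_not_installed("pROC")
  proc <- suppressMessages(as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                          direction = "<",
                                                          quiet = TRUE))))
  expect_equal(auc, proc, tolerance = 1e-10)
})

test_that("AUC edge cases: separation, null, monotone invariance", {
  truth <- rep(c(TRUE, FALSE), each = 25)
  expect_equal(score_auc(c(rep(2, 25), rep(1, 25)), truth), 1)
  set.seed(63)
  null_scores <- rnorm(10000)
  null_truth <- rep(c(TRUE, FALSE), 5000)
  expect_lt(abs(score_auc(null_scores, null_truth) - 0.5), 0.02)
  s <- runif(50)
  expect_equal(score_auc(s, truth), score_auc(exp(3 * s) + 5, truth))
  expect_error(score_auc(s, rep(TRUE, 50)), "both classes")
})
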