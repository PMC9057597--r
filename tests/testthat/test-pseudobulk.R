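sc_fixture <- function() {
  genes <- paste0("g", 1:5)
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:7),
    cell_type = c("T", "T", "T", "B", "B", "T", "B"),
    sample_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"))
  counts <- matrix(1L, 7, 5, dimnames = list(cells$cell_id, genes))
  counts["c1", "g1"] <- 1L; counts["c2", "g1"] <- 2L; counts["c3", "g1"] <- 3L
  counts["c6", ] <- 9L
  samples <- tibble::tibble(sample_id = c("s1", "s2"), time = c(0, 1))
  list(counts = counts, cells = cells, samples = samples)
}

test_that("pooling sums counts per gene per sample and records cells", {
  fx <- sc_fixture()
  pb <- aggregate_pseudobulk(fx$counts, fx$cells, fx$samples, "T")
  expect_equal(pb$counts["g1", "s1"], 6)           # 1 + 2 + 3
  expect_equal(unname(pb$counts[, "s2"]), rep(9, 5))  # single cell column
  expect_equal(pb$samples$n_cells, c(3L, 1L))

  # order invariance
  ord <- sample(nrow(fx$cells))
  pb2 <- aggregate_pseudobulk(fx$counts[ord, ], fx$cells[ord, ], fx$samples, "T")
  expect_equal(pb2$counts[, colnames(pb$counts)], pb$counts)

  # conservation: pooled totals equal the single-cell totals of that type
  tcells <- fx$cells$cell_id[fx$cells$cell_type == "T"]
  expect_equal(sum(pb$counts), sum(fx$counts[tcells, ]))

  expect_error(aggregate_pseudobulk(fx$counts, fx$cells, fx$samples, "NK"),
               "unknown cell type")
})

test_that("sparse input pools identically to dense", {
  fx <- sc_fixture()
  sp <- Matrix::Matrix(fx$counts, sparse = TRUE)
  pb_d <- aggregate_pseudobulk(fx$counts, fx$cells, fx$samples, "B")
  pb_s <- aggregate_pseudobulk(sp, fx$cells, fx$samples, "B")
  expect_equal(pb_s$counts, pb_d$counts)
})

test_that("cell-type filter applies the inclusive 1000-cell rule per scope", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:2999),
    cell_type = c(rep("big", 2000), rep("edge", 999)),
    sample_id = rep(c("s1", "s2"), length.out = 2999))
  samples <- tibble::tibble(sample_id = c("s1", "s2"), time = c(0, 1))
  expect_equal(filter_cell_types(cells, samples, min_cells = 1000), "big")
  # per-time: "big" has exactly 1000 at each time -> retained (inclusive)
  expect_equal(filter_cell_types(cells, samples, min_cells = 1000,
                                 scope = "per-time"), "big")
  expect_equal(filter_cell_types(cells, samples, min_cells = 1,
                                 scope = "global"),
               c("big", "edge"))
  # edge has 500 at s1, 499 at s2 -> dropped at per-time threshold 500
  expect_equal(filter_cell_types(cells, samples, min_cells = 500,
                                 scope = "per-time"), "big")
})

test_that("low-expression filter keeps CPM >= min_cpm in enough samples", {
  fx <- sc_fixture()
  pb <- aggregate_pseudobulk(fx$counts, fx$cells, fx$samples, "T")
  pb$counts <- rbind(pb$counts,
                     g_zero = c(0, 0),
                     g_one_sample = c(5000, 0))
  kept <- filter_low_expression(pb, min_cpm = 1, min_samples = 1)
  expect_false("g_zero" %in% rownames(kept$counts))
  expect_true("g_one_sample" %in% rownames(kept$counts))
  # boundary: passing in exactly min_samples - 1 samples removes the gene
  kept2 <- filter_low_expression(pb, min_cpm = 1, min_samples = 2)
  expect_false("g_one_sample" %in% rownames(kept2$counts))
  expect_error(filter_low_expression(pb, min_cpm = 1e9), "all genes filtered")
})

test_that("RLE normalization has unit factors for identical samples", {
  counts <- matrix(rep(c(10, 40, 90, 200), 3), 4, 3,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  pb <- structure(list(cell_type = "T", counts = counts,
                       samples = tibble::tibble(sample_id = paste0("s", 1:3),
                                                time = 0:2, n_cells = 1)),
                  class = "pseudobulk")
  nm <- normalize_pseudobulk(pb)
  expect_equal(unname(nm$size_factors), rep(1, 3))
})

test_that("a 2x-scaled sample gets factor 2 and identical normalized values", {
  set.seed(8)
  a <- rpois(50, 60) + 1L
  counts <- cbind(s1 = a, s2 = 2L * a)
  rownames(counts) <- paste0("g", 1:50)
  pb <- structure(list(cell_type = "T", counts = counts,
                       samples = tibble::tibble(sample_id = c("s1", "s2"),
                                                time = 0:1, n_cells = 1)),
                  class = "pseudobulk")
  nm <- normalize_pseudobulk(pb)
  expect_equal(nm$size_factors[["s2"]] / nm$size_factors[["s1"]], 2,
               tolerance = 1e-12)
  expect_lt(max(abs(nm$norm_logcpm[, 1] - nm$norm_logcpm[, 2])), 1e-9)
})

test_that("logCPM arithmetic and idempotence hold", {
  # count 100 in an effective library of 1e6 -> CPM 100 -> log2(101)
  counts <- cbind(s1 = c(100, 1e6 - 100), s2 = c(100, 1e6 - 100))
  rownames(counts) <- c("g1", "g2")
  pb <- structure(list(cell_type = "T", counts = counts,
                       samples = tibble::tibble(sample_id = c("s1", "s2"),
                                                time = 0:1, n_cells = 1)),
                  class = "pseudobulk")
  nm <- normalize_pseudobulk(pb)
  expect_equal(nm$norm_logcpm["g1", "s1"], log2(101), tolerance = 1e-9)

  # renormalizing already-normalized counts: factors within 1e-6 of 1
  set.seed(13)
  counts2 <- matrix(rpois(80, 200) + 1, 20, 4,
                    dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  counts2[, 2] <- counts2[, 2] * 3
  sf1 <- rle_size_factors(counts2)
  renorm <- sweep(counts2, 2, sf1, "/")
  expect_lt(max(abs(rle_size_factors(renorm) - 1)), 1e-6)
})

test_that("pseudobulk converts to a time-course experiment", {
  fx <- sc_fixture()
  pb <- aggregate_pseudobulk(fx$counts, fx$cells, fx$samples, "T")
  expt <- pseudobulk_experiment(pb, baseline_time = 0)
  expect_s3_class(expt, "tc_experiment")
  expect_equal(unname(expt$counts["g1", ]), unname(pb$counts["g1", ]))

  pb$counts[, 1] <- 0
  expect_error(normalize_pseudobulk(pb), "all-zero")
})
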