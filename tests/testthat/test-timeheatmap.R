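# a 3-gene fake fit over times 0 (baseline, mu 100) .. 3:
#   g_up doubles each window (delta log2 ~ +1)
#   g_biphasic peaks at t1 then falls
#   g_flat stays at baseline
th_fixture <- function() {
  mu <- rbind(
    g_up = c(200, 400, 800),
    g_biphasic = c(400, 100, 25),
    g_flat = c(100, 100, 100))
  fake_trend_catch(mu, times = 1:3, mu_baseline = c(100, 100, 100))
}

test_that("window gene sets capture directional movement", {
  ws <- window_gene_sets(th_fixture(), delta_log2 = 0.25)
  w1 <- ws[ws$t_start == 0, ]
  expect_setequal(w1$gene_id[w1$direction == "up"], c("g_up", "g_biphasic"))
  expect_false("g_flat" %in% ws$gene_id)
  # biphasic: up early, down later
  expect_equal(ws$direction[ws$gene_id == "g_biphasic" & ws$t_start == 1], "down")
  # doubling gene has delta ~ 1 in window (0,1): log2(201/101)
  d <- ws$delta[ws$gene_id == "g_up" & ws$t_start == 0]
  expect_equal(d, log2(201 / 101), tolerance = 1e-12)
  # no gene in both directions within one window
  dup <- ws |> dplyr::count(window, gene_id) |> dplyr::pull(n)
  expect_true(all(dup == 1))
})

test_that("flat input yields empty window sets", {
  mu <- rbind(g1 = c(100, 100, 100))
  tc <- fake_trend_catch(mu, 1:3, 100)
  expect_equal(nrow(window_gene_sets(tc)), 0)
})

test_that("window enrichment is one-sided Fisher over the universe", {
  universe <- paste0("g", 1:1000)
  set1 <- paste0("g", 1:50)
  lst <- paste0("g", c(1:10, 500:514))       # 10 in set, 15 outside
  enr <- enrich_window(lst, list(S = set1), universe)
  oracle <- fisher_greater_bruteforce(10, 15, 40, 935)
  expect_equal(enr$pvalue, oracle, tolerance = 1e-10)

  disjoint <- enrich_window(paste0("g", 900:920), list(S = set1), universe)
  expect_equal(disjoint$pvalue, 1)

  # relabeling invariance
  map <- setNames(paste0("x", 1:1000), universe)
  enr2 <- enrich_window(unname(map[lst]), list(S = unname(map[set1])), unname(map))
  expect_equal(enr2$pvalue, enr$pvalue)

  expect_error(enrich_window(lst, list(S = set1), character(0)), "empty universe")
})

test_that("Fisher exact p agrees with hypergeometric summation on small tables", {
  grid <- expand.grid(a = c(0, 1, 3, 7), b = c(0, 2, 9),
                      c_ = c(1, 5, 12), d = c(8, 18, 30))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; c_ <- grid$c_[i]; d <- grid$d[i]
    universe <- paste0("g", seq_len(a + b + c_ + d))
    lst <- universe[seq_len(a + b)]
    st <- universe[c(seq_len(a), a + b + seq_len(c_))]
    p <- enrich_window(lst, list(S = st), universe)$pvalue
    expect_equal(p, fisher_greater_bruteforce(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("TimeHeatmap cells average member deltas and rows sum exactly", {
  tc <- th_fixture()
  sets <- list(PW = c("g_up", "g_biphasic"), OTHER = "g_flat")
  th <- build_timeheatmap(tc, sets, top_k = 2)
  tab <- tidy(th)
  # window (0,1): both members moved up by log2(201/101), log2(401/101)
  cell <- tab[tab$set == "PW" & tab$t_start == 0, ]
  expect_equal(cell$avg_log2fc, mean(c(log2(201 / 101), log2(401 / 101))),
               tolerance = 1e-12)
  # row-sum identity
  sums <- tab |> dplyr::group_by(set) |> dplyr::summarise(s = sum(avg_log2fc))
  expect_equal(th$summary$go_mean_logfc[match(sums$set, th$summary$set)],
               sums$s, tolerance = 1e-12)
  # pct_go arithmetic
  expect_equal(th$summary$pct_go[th$summary$set == "PW"], 100)
})

test_that("pct_go reproduces the printed-percentage arithmetic", {
  expect_equal(100 * 117 / 500, 23.4)
  mu <- matrix(c(200, 400, 800), 1, dimnames = list("g_up", NULL))
  tc <- fake_trend_catch(mu, 1:3, 100)
  sets <- list(S = c("g_up", paste0("pad", 1:4)))
  th <- build_timeheatmap(tc, sets, top_k = 1)
  expect_equal(th$summary$n_ddeg, 1)
  expect_equal(th$summary$pct_go, 20)
})

test_that("two-sided bar splits by sign with name tie-break", {
  tc <- th_fixture()
  sets <- list(UPPATH = "g_up", DOWNPATH = "g_biphasic")
  th <- build_timeheatmap(tc, sets, top_k = 2)
  bar <- two_sided_bar(th, n_top = 2)
  expect_equal(bar$side[bar$set == "UPPATH"], "positive")
  expect_equal(bar$side[bar$set == "DOWNPATH"], "negative")

  # symmetric constructed summary: one pathway each side, ties by name
  th2 <- th
  th2$summary <- tibble::tibble(set = c("B", "A", "C"),
                                go_mean_logfc = c(1, 1, -1),
                                n_ddeg = 1, set_size = 1, pct_go = 100)
  bar2 <- two_sided_bar(th2, n_top = 1)
  expect_equal(bar2$set, c("A", "C"))
})

test_that("GMT collections round-trip and reject duplicates", {
  sets <- list(ALPHA = c("g1", "g2", "g3"), BETA = c("g2", "g9"))
  path <- write_gmt(sets, tempfile(fileext = ".gmt"))
  back <- read_gmt(path)
  expect_equal(back, sets)
  writeLines(c("S\tna\tg1", "S\tna\tg2"), dup <- tempfile(fileext = ".gmt"))
  expect_error(read_gmt(dup), "duplicate set names")
})

test_that("empty collections error and plots build", {
  tc <- th_fixture()
  expect_error(build_timeheatmap(tc, list()), "empty gene-set collection")
  th <- build_timeheatmap(tc, list(PW = c("g_up", "g_biphasic")), top_k = 1)
  expect_s3_class(autoplot(th), "ggplot")
})
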