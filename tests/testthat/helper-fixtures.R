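# Fixtures built in code: small experiments and a hand-assembled trend_catch
# whose fitted trajectories are set exactly (for arithmetic-level checks of
# the window/TimeHeatmap machinery).

make_expt <- function(counts, times, baseline_time = times[1]) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  reps <- stats::ave(seq_along(times), times, FUN = seq_along)
  meta <- data.frame(sample_id = colnames(counts), time = times, replicate = reps)
  time_course_experiment(counts, meta, baseline_time)
}

# experiment with one gene whose counts are `value` at every sample
constant_expt <- function(value = 20, times = rep(0:4, each = 3)) {
  make_expt(matrix(value, 1, length(times)), times)
}

# trend_catch with prescribed fitted means: mu is a genes x times matrix over
# non-baseline `times`; every gene is flagged DDEG
fake_trend_catch <- function(mu, times, mu_baseline, baseline_time = 0,
                             gene_ids = rownames(mu), unit = "D") {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(mu)))
  fits <- lapply(seq_len(nrow(mu)), function(i) {
    trendcurve:::new_tc_spline(times, mu[i, ], 1, length(times), "gcv", TRUE)
  })
  names(fits) <- gene_ids
  master <- tibble::tibble(
    gene_id = gene_ids, mu_baseline = mu_baseline,
    dispersion = 0.1, gene_pvalue = 1e-6, gene_pvalue_adj = 1e-5,
    is_ddeg = TRUE, master_pattern = "up", sub_pattern = "up"
  )
  structure(list(master = master, fits = fits, times = times,
                 baseline_time = baseline_time,
                 params = list(alpha = 0.05, ci_level = 0.9,
                               p_threshold = 0.05, time_unit_label = unit,
                               criterion = "gcv")),
            class = "trend_catch")
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# brute-force NB quantile by pmf summation
nb_quantile_bruteforce <- function(p, mu, phi) {
  k <- 0; acc <- 0
  pmf <- function(x) if (phi <= 1e-12) dpois(x, mu) else dnbinom(x, size = 1 / phi, mu = mu)
  repeat {
    acc <- acc + pmf(k)
    if (acc >= p) return(k)
    k <- k + 1
    if (k > 1e6) stop("runaway summation")
  }
}

# brute-force upper/lower NB tail by pmf summation
nb_tail_bruteforce <- function(q, mu, phi, lower = TRUE) {
  pmf <- function(x) if (phi <= 1e-12) dpois(x, mu) else dnbinom(x, size = 1 / phi, mu = mu)
  if (lower) return(sum(pmf(0:q)))
  # sum the upper tail outward (avoids 1 - sum cancellation)
  acc <- 0; k <- q
  repeat {
    term <- pmf(k)
    acc <- acc + term
    if (term < acc * 1e-17 + 1e-300) return(acc)
    k <- k + 1
  }
}

# one-sided hypergeometric enrichment p by direct summation over the
# 2x2 table a (in set & in list), b (list only), c (set only), d (neither)
fisher_greater_bruteforce <- function(a, b, c_, d) {
  K <- a + c_          # set size
  n <- a + b           # list size
  N <- a + b + c_ + d
  xs <- a:min(K, n)
  sum(dhyper(xs, K, N - K, n))
}
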