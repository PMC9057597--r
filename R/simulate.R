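#' Embedded mean trajectory for one simulated gene
#'
#' Builds the noiseless per-timepoint mean curve of one trajectory class on
#' an evenly indexed time course:
#' * `nondynamic` — constant at the baseline mean;
#' * `monotonic` — log2 expression changes linearly to an endpoint change of
#'   `effect` log2 units (sign by `direction`);
#' * `one_break` / `two_break` / `three_break` — alternating up/down
#'   segments anchored at randomly placed interior break times, each segment
#'   spanning an `effect`-range log2 change, linear in log2 between anchors.
#'
#' For the multi-break classes segment effects are rejection-sampled so that
#' every anchor sits at least half the minimum effect away from baseline in
#' log2 units; an inflection anchored exactly at baseline would be
#' indistinguishable from no change and would make the truth label
#' ill-defined.
#'
#' @param class One of `"nondynamic"`, `"monotonic"`, `"one_break"`,
#'   `"two_break"`, `"three_break"`.
#' @param n_timepoints Number of time points (needs >= breaks + 2).
#' @param effect Length-2 log2FC range for segment effects (default
#'   `c(0.5, 2)`), or a single value used exactly.
#' @param baseline Baseline mean count (default 100).
#' @param direction First segment direction: `"random"` (default), `"up"` or
#'   `"down"`.
#' @return Positive numeric vector of per-timepoint means, with attributes
#'   `break_times` (indices into `0:(n_timepoints-1)`) and `log2_anchors`.
#' @export
mean_curve <- function(class = c("nondynamic", "monotonic", "one_break",
                                 "two_break", "three_break"),
                       n_timepoints, effect = c(0.5, 2), baseline = 100,
                       direction = c("random", "up", "down")) {
  class <- match.arg(class)
  direction <- match.arg(direction)
  if (length(effect) == 1) effect <- c(effect, effect)
  n_breaks <- switch(class, nondynamic = 0L, monotonic = 0L,
                     one_break = 1L, two_break = 2L, three_break = 3L)
  if (class != "nondynamic" && n_timepoints < n_breaks + 2) {
    stop(class, " needs at least ", n_breaks + 2, " timepoints")
  }
  tt <- seq_len(n_timepoints) - 1
  if (class == "nondynamic") {
    mu <- rep(baseline, n_timepoints)
    attr(mu, "break_times") <- numeric(0)
    attr(mu, "log2_anchors") <- c(0, 0)
    return(mu)
  }
  sgn <- switch(direction, up = 1, down = -1,
                random = sample(c(-1, 1), 1))
  draw <- function() runif(1, effect[1], effect[2])
  margin <- effect[1] / 2
  if (class == "monotonic") {
    anchors_t <- c(0, n_timepoints - 1)
    anchors_v <- c(0, sgn * draw())
  } else {
    bt <- sort(sample(seq_len(n_timepoints - 2), n_breaks))  # interior indices
    anchors_t <- c(0, bt, n_timepoints - 1)
    anchors_v <- 0
    s <- sgn
    for (k in seq_len(n_breaks + 1)) {
      last <- anchors_v[length(anchors_v)]
      for (try in 1:100) {
        v <- last + s * draw()
        if (abs(v) >= margin) break
      }
      anchors_v <- c(anchors_v, v)
      s <- -s
    }
  }
  l2 <- stats::approx(anchors_t, anchors_v, xout = tt)$y
  mu <- baseline * 2^l2
  attr(mu, "break_times") <- if (class == "monotonic") numeric(0) else anchors_t[2:(length(anchors_t) - 1)]
  attr(mu, "log2_anchors") <- anchors_v
  mu
}

#' Add negative-binomial noise to an embedded trajectory
#'
#' Draws `n_replicates` independent NB(mean, phi) counts per time point.
#'
#' @param means Positive per-timepoint means.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2); `phi <= 1e-12`
#'   gives Poisson counts.
#' @param n_replicates Replicates per time point (default 3).
#' @return Integer matrix, `n_timepoints` rows x `n_replicates` columns.
#' @export
add_nb_noise <- function(means, dispersion, n_replicates = 3) {
  stopifnot(all(means > 0))
  matrix(nb_rand(length(means) * n_replicates, mu = rep(means, n_replicates),
                 phi = dispersion),
         nrow = length(means))
}

#' Simulate a benchmark time-course data set with ground truth
#'
#' Generates the mixed-trajectory benchmark: `n_genes` genes split across
#' five trajectory classes by `fractions` (largest-remainder rounding, so
#' class counts are exact), evenly spaced time points `0, 1, ...`,
#' `n_replicates` NB-noise replicates per time point.  Baseline means are
#' drawn log-uniformly from `baseline_range` and each gene's dispersion
#' follows the decreasing mean-dispersion trend
#' `phi = disp_a / mu + disp_b`.  Monotonic endpoint changes and per-segment
#' changes of the break classes are drawn from `effect_range` log2FC.
#'
#' @param n_genes Number of genes (default 10000).
#' @param n_timepoints Number of evenly spaced time points (default 7).
#' @param n_replicates Replicates per time point (default 3).
#' @param fractions Named class fractions summing to 1 (defaults: 90%
#'   nondynamic, 2.5% each monotonic / one / two / three break).
#' @param effect_range Segment log2FC range, default `c(0.5, 2)`.
#' @param baseline_range Baseline mean range, default `c(20, 2000)`.
#' @param disp_a,disp_b Mean-dispersion trend coefficients (default 3, 0.05).
#' @param noiseless Use exact rounded means for every replicate instead of
#'   NB noise (for deterministic recovery benchmarks).
#' @param seed RNG seed.
#' @return A `tc_simulation` list: `expt` (a [time_course_experiment()] with
#'   baseline time 0) and `truth` (tibble `gene_id`, `class`,
#'   `truth_dynamic`, `n_break_points`, `dispersion`, `baseline_mean`).
#' @export
simulate_time_course <- function(n_genes = 10000, n_timepoints = 7,
                                 n_replicates = 3,
                                 fractions = c(nondynamic = 0.90,
                                               monotonic = 0.025,
                                               one_break = 0.025,
                                               two_break = 0.025,
                                               three_break = 0.025),
                                 effect_range = c(0.5, 2),
                                 baseline_range = c(20, 2000),
                                 disp_a = 3, disp_b = 0.05,
                                 noiseless = FALSE, seed = 1) {
  stopifnot(n_timepoints >= 3, abs(sum(fractions) - 1) < 1e-8)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  counts_per_class <- largest_remainder(fractions, n_genes)
  classes <- rep(names(counts_per_class), counts_per_class)
  n_breaks_of <- c(nondynamic = 0L, monotonic = 0L, one_break = 1L,
                   two_break = 2L, three_break = 3L)

  tt <- seq_len(n_timepoints) - 1
  sample_time <- rep(tt, each = n_replicates)
  counts <- matrix(0L, n_genes, length(sample_time))
  truth_bp <- integer(n_genes)
  endpoint <- numeric(n_genes)
  base_mu <- exp(runif(n_genes, log(baseline_range[1]), log(baseline_range[2])))
  phi <- disp_a / base_mu + disp_b

  # a course with T timepoints can express at most T - 2 interior breaks;
  # classes beyond that are generated at the feasible maximum (the gene is
  # still dynamic and multiphasic as far as the course can express)
  cap <- max(n_timepoints - 2L, 1L)
  feasible <- vapply(names(n_breaks_of), function(cl) {
    if (n_breaks_of[[cl]] == 0L) cl
    else c("one_break", "two_break", "three_break")[min(n_breaks_of[[cl]], cap)]
  }, character(1))

  for (i in seq_len(n_genes)) {
    mu <- mean_curve(feasible[[classes[i]]], n_timepoints,
                     effect = effect_range, baseline = base_mu[i])
    truth_bp[i] <- length(attr(mu, "break_times"))
    anch <- attr(mu, "log2_anchors")
    endpoint[i] <- anch[length(anch)]
    counts[i, ] <- if (noiseless) {
      rep(pmax(round(mu), 1), each = n_replicates)
    } else {
      as.integer(t(add_nb_noise(mu, phi[i], n_replicates)))
    }
  }
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  rownames(counts) <- gene_ids
  colnames(counts) <- sprintf("t%s_r%d", format_time(sample_time),
                              rep(seq_len(n_replicates), n_timepoints))
  meta <- tibble::tibble(sample_id = colnames(counts), time = sample_time,
                         replicate = rep(seq_len(n_replicates), n_timepoints))
  expt <- time_course_experiment(counts, meta, baseline_time = 0)
  truth <- tibble::tibble(gene_id = gene_ids, class = classes,
                          truth_dynamic = classes != "nondynamic",
                          n_break_points = truth_bp,
                          endpoint_log2fc = endpoint,
                          dispersion = phi, baseline_mean = base_mu)
  structure(list(expt = expt, truth = truth,
                 params = list(n_timepoints = n_timepoints,
                               n_replicates = n_replicates, seed = seed,
                               noiseless = noiseless)),
            class = "tc_simulation")
}

# exact integer apportionment of n by fractions
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Rank-based ROC AUC of a dynamic-gene score
#'
#' Mann-Whitney estimate: the probability that a random truly dynamic gene
#' scores above a random non-dynamic one (ties count half), computed from
#' average ranks.
#'
#' @param scores Per-gene score, larger = more dynamic (the pipeline's score
#'   is `-log10(gene_pvalue)`).
#' @param truth_dynamic Logical ground-truth labels.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores, truth_dynamic) {
  stopifnot(length(scores) == length(truth_dynamic))
  truth_dynamic <- as.logical(truth_dynamic)
  n1 <- sum(truth_dynamic); n0 <- sum(!truth_dynamic)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[truth_dynamic]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the DDEG caller on a simulation and report the ROC AUC
#'
#' Convenience wrapper: [catch_trends()] on the simulated experiment, genes
#' scored by `-log10(gene_pvalue)` against the simulation's truth labels.
#'
#' @param sim A `tc_simulation` from [simulate_time_course()].
#' @param ... Passed to [catch_trends()].
#' @return List with `auc` and the `trend_catch` fit.
#' @export
benchmark_auc <- function(sim, ...) {
  stopifnot(inherits(sim, "tc_simulation"))
  tc <- catch_trends(sim$expt, ...)
  stopifnot(identical(tc$master$gene_id, sim$truth$gene_id))
  score <- -log10(pmax(tc$master$gene_pvalue, 1e-300))
  list(auc = score_auc(score, sim$truth$truth_dynamic), fit = tc)
}
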