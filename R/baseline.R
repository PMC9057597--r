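#' Fit the baseline fluctuation model for one gene
#'
#' The baseline count of a gene is modelled as NB(mu, phi) with the
#' dispersion phi held fixed.  With phi fixed the NB maximum-likelihood
#' estimate of the mean is the sample mean of the baseline counts (the NB
#' log-likelihood's score in mu is `sum((y - mu) / (mu (1 + phi mu)))`, whose
#' unique zero is `mu = mean(y)`), so `mu_baseline` is the baseline sample
#' mean.  The baseline fluctuation interval is the central `ci_level`
#' probability band of the discrete NB law: the 5% and 95% quantiles for the
#' default 90% level.  Discrete quantiles make the interval conservative
#' (coverage at least the nominal level).
#'
#' A gene with `mu_baseline = 0` has no defined NB law; a pseudo-mean of 0.5
#' counts is substituted for interval and tail computations and the model is
#' flagged (`zero_baseline = TRUE`).
#'
#' @param expt A [time_course_experiment()].
#' @param gene Gene id.
#' @param dispersion Fixed dispersion phi (>= 0), e.g. from
#'   [estimate_dispersion()].
#' @param ci_level Central coverage of the fluctuation interval, default 0.9.
#' @return A `tc_baseline` list: `gene_id`, `mu_baseline`, `dispersion`,
#'   `ci_low`, `ci_high`, `ci_level`, `zero_baseline`.
#' @export
fit_baseline <- function(expt, gene, dispersion, ci_level = 0.9) {
  stopifnot(inherits(expt, "tc_experiment"),
            dispersion >= 0, ci_level > 0, ci_level < 1)
  if (!gene %in% rownames(expt$counts)) stop("unknown gene id: ", gene)
  base <- expt$metadata$time == expt$baseline_time
  if (!any(base)) stop("no baseline samples at time ", expt$baseline_time)
  y <- expt$counts[gene, base]
  mu <- mean(y)
  zero <- mu == 0
  mu_eff <- if (zero) 0.5 else mu
  a <- (1 - ci_level) / 2
  structure(list(
    gene_id = gene,
    mu_baseline = mu,
    dispersion = dispersion,
    ci_low = nb_quantile(a, mu_eff, dispersion),
    ci_high = nb_quantile(1 - a, mu_eff, dispersion),
    ci_level = ci_level,
    zero_baseline = zero
  ), class = "tc_baseline")
}
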