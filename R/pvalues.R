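#' Per-timepoint dynamic p-values against the baseline fluctuation law
#'
#' For each non-baseline time the fitted mean is tested against the gene's
#' baseline NB(mu_baseline, phi) distribution: if the fitted mean is at or
#' above the baseline mean, the p-value is the upper tail mass
#' `P(X >= ceiling(mu_t))`; otherwise the lower tail `P(X <= floor(mu_t))`.
#' Rounding the (continuous) fitted mean outward to the discrete support
#' makes the tail conservative and well-defined.  A zero baseline mean uses
#' the pseudo-mean 0.5 substituted by [fit_baseline()].
#'
#' @param fit A `tc_spline` from [fit_trajectory()].
#' @param baseline A `tc_baseline` from [fit_baseline()].
#' @return Tibble with columns `time`, `fitted_mu`, `pvalue`.
#' @export
timepoint_pvalue <- function(fit, baseline) {
  stopifnot(inherits(fit, "tc_spline"), inherits(baseline, "tc_baseline"))
  mu_b <- if (baseline$zero_baseline) 0.5 else baseline$mu_baseline
  phi <- baseline$dispersion
  p <- vapply(fit$fitted_mu, function(mu_t) {
    if (mu_t >= mu_b) nb_tail(ceiling(mu_t), mu_b, phi, lower = FALSE)
    else nb_tail(floor(mu_t), mu_b, phi, lower = TRUE)
  }, numeric(1))
  tibble::tibble(time = fit$times, fitted_mu = fit$fitted_mu,
                 pvalue = pmin(pmax(p, 0), 1))
}

#' Combine per-timepoint p-values with Fisher's method
#'
#' `X2 = -2 sum(log p)` is referred to the chi-square distribution with `2K`
#' degrees of freedom (K p-values).  Exact zeros are floored at 1e-300 before
#' taking logs.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @examples
#' combine_pvalues(c(0.05, 0.05)) # ~0.0175
#' @export
combine_pvalues <- function(p) {
  if (length(p) == 0) stop("cannot combine an empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p <- pmax(p, 1e-300)
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Holm-Bonferroni adjustment and DDEG flagging
#'
#' Adjusts gene-level dynamic p-values across genes by Holm's step-down
#' procedure and flags genes with adjusted p below `alpha` as dynamic
#' differentially expressed (DDEG).
#'
#' @param master A data frame with a `gene_pvalue` column (e.g. the master
#'   table from [catch_trends()]).
#' @param alpha Significance threshold, default 0.05.
#' @return The input with columns `gene_pvalue_adj` and `is_ddeg`
#'   added/overwritten.
#' @export
adjust_and_flag <- function(master, alpha = 0.05) {
  stopifnot(is.data.frame(master), "gene_pvalue" %in% names(master))
  master$gene_pvalue_adj <- p.adjust(master$gene_pvalue, method = "holm")
  master$is_ddeg <- master$gene_pvalue_adj < alpha
  master
}
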