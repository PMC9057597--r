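#' Identify dynamic differentially expressed genes in a time course
#'
#' Runs the full per-gene pipeline on a preprocessed experiment:
#'
#' 1. per-gene NB dispersion ([estimate_dispersion()]);
#' 2. baseline NB model and 90% fluctuation interval ([fit_baseline()]);
#' 3. penalized NB smoothing-spline trajectory over the non-baseline samples
#'    ([fit_trajectory()]);
#' 4. per-timepoint tail p-values of the fitted means against the baseline
#'    law ([timepoint_pvalue()]) and their Fisher combination
#'    ([combine_pvalues()]);
#' 5. Holm-Bonferroni adjustment across genes and DDEG flagging
#'    ([adjust_and_flag()]);
#' 6. break-point screening and trajectory pattern assignment
#'    ([assign_pattern()]), on the raw per-time p-values.
#'
#' @param expt A [time_course_experiment()], typically after [preprocess()].
#' @param alpha Gene-level significance threshold on the adjusted p (DDEG
#'   flag), default 0.05.
#' @param ci_level Baseline fluctuation interval coverage, default 0.9.
#' @param p_threshold Raw per-time p threshold used for pattern segmentation,
#'   default 0.05.
#' @param time_unit_label Unit suffix for pattern anchors (default `"D"`).
#' @param lambda_grid,criterion Passed to [fit_trajectory()].
#' @param verbose Print progress every 1000 genes.
#' @return A `trend_catch` object.  `tidy()` returns the master table, one
#'   row per gene: `gene_id`, `mu_baseline`, `dispersion`, `ci_low`,
#'   `ci_high`, wide fitted-mean columns `mu_t_<time>`, per-time p columns
#'   `p_t_<time>`, `gene_pvalue`, `gene_pvalue_adj`, `is_ddeg`,
#'   `master_pattern`, `sub_pattern`, `break_points` (times joined with
#'   `";"`). `glance()` returns one-row run summary.
#' @examples
#' sim <- simulate_time_course(n_genes = 50, n_timepoints = 5, seed = 7)
#' fit <- catch_trends(sim$expt)
#' glance(fit)
#' @export
catch_trends <- function(expt, alpha = 0.05, ci_level = 0.9,
                         p_threshold = 0.05, time_unit_label = "D",
                         lambda_grid = 10^seq(-3, 3, length.out = 13),
                         criterion = c("gcv", "aic"), verbose = FALSE) {
  stopifnot(inherits(expt, "tc_experiment"))
  criterion <- match.arg(criterion)
  genes <- rownames(expt$counts)
  grp <- factor(expt$metadata$time)
  base_idx <- expt$metadata$time == expt$baseline_time
  nb_idx <- !base_idx
  tt_nb <- expt$metadata$time[nb_idx]
  times_nb <- sort(unique(tt_nb))
  if (length(times_nb) < 1) stop("need at least one non-baseline time")
  a <- (1 - ci_level) / 2

  rows <- vector("list", length(genes))
  fits <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    y_all <- expt$counts[k, ]
    phi <- dispersion_one(y_all, grp)[1]

    y_base <- y_all[base_idx]
    mu_b <- mean(y_base)
    zero_b <- mu_b == 0
    mu_b_eff <- if (zero_b) 0.5 else mu_b
    ci_low <- nb_quantile(a, mu_b_eff, phi)
    ci_high <- nb_quantile(1 - a, mu_b_eff, phi)

    fit <- fit_trajectory_raw(y_all[nb_idx], tt_nb, phi, lambda_grid, criterion)
    mu_t <- fit$fitted_mu
    p_t <- vapply(mu_t, function(m) {
      if (m >= mu_b_eff) nb_tail(ceiling(m), mu_b_eff, phi, lower = FALSE)
      else nb_tail(floor(m), mu_b_eff, phi, lower = TRUE)
    }, numeric(1))
    p_t <- pmin(pmax(p_t, 0), 1)
    gene_p <- combine_pvalues(p_t)

    pat <- assign_pattern(fit$times, mu_t, p_t, expt$baseline_time, mu_b,
                          p_threshold, time_unit_label)

    rows[[k]] <- c(list(gene_id = genes[k], mu_baseline = mu_b,
                        dispersion = phi, ci_low = ci_low, ci_high = ci_high),
                   setNames(as.list(mu_t), paste0("mu_t_", format_time(fit$times))),
                   setNames(as.list(p_t), paste0("p_t_", format_time(fit$times))),
                   list(gene_pvalue = gene_p,
                        master_pattern = pat$master_pattern,
                        sub_pattern = pat$sub_pattern,
                        break_points = paste(format_time(pat$break_points$time),
                                             collapse = ";"),
                        n_break_points = nrow(pat$break_points),
                        spline_converged = fit$converged))
    fits[[k]] <- fit
    if (verbose && k %% 1000 == 0) message(k, " / ", length(genes), " genes fitted")
  }
  master <- dplyr::bind_rows(rows)
  master <- adjust_and_flag(master, alpha)
  master <- dplyr::relocate(master, "gene_pvalue_adj", "is_ddeg",
                            .after = "gene_pvalue")
  names(fits) <- genes

  structure(list(
    master = master,
    fits = fits,
    times = times_nb,
    baseline_time = expt$baseline_time,
    params = list(alpha = alpha, ci_level = ci_level,
                  p_threshold = p_threshold,
                  time_unit_label = time_unit_label, criterion = criterion)
  ), class = "trend_catch")
}

#' @export
print.trend_catch <- function(x, ...) {
  cat("<trend_catch> ", nrow(x$master), " genes, ",
      sum(x$master$is_ddeg), " DDEGs (alpha = ", x$params$alpha, ")\n", sep = "")
  cat("  times: ", format_time(x$baseline_time), " (baseline) + ",
      paste(format_time(x$times), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn catch_trends Master table, one row per gene.
#' @param x,object A `trend_catch` object.
#' @param ... Unused.
#' @export
tidy.trend_catch <- function(x, ...) x$master

#' @describeIn catch_trends One-row run summary (gene, DDEG and time counts,
#'   thresholds).
#' @export
glance.trend_catch <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$master),
    n_ddeg = sum(x$master$is_ddeg),
    n_times = length(x$times) + 1L,
    baseline_time = x$baseline_time,
    alpha = x$params$alpha,
    ci_level = x$params$ci_level
  )
}

#' Baseline-relative log2 fold-change profiles of fitted trajectories
#'
#' For each selected gene, the fitted mean at every non-baseline time
#' expressed as log2((mu_t + 1) / (mu_baseline + 1)) — the per-gene
#' trajectory relative to its own baseline, the unit used by the group
#' comparison module.
#'
#' @param tc A `trend_catch`.
#' @param genes Gene ids (default: the DDEGs).
#' @return Tibble `gene_id`, `time`, `log2fc`.
#' @export
ddeg_profiles <- function(tc, genes = NULL) {
  stopifnot(inherits(tc, "trend_catch"))
  if (is.null(genes)) genes <- tc$master$gene_id[tc$master$is_ddeg]
  genes <- intersect(genes, tc$master$gene_id)
  mu_b <- tc$master$mu_baseline[match(genes, tc$master$gene_id)]
  purrr::map2_dfr(genes, mu_b, function(g, mb) {
    f <- tc$fits[[g]]
    tibble::tibble(gene_id = g, time = f$times,
                   log2fc = log2((f$fitted_mu + 1) / (mb + 1)))
  })
}

#' Plot observed counts and fitted trajectories for a few genes
#'
#' @param object A `trend_catch`.
#' @param genes Gene ids to draw (default: up to 6 top DDEGs).
#' @param expt Optionally the `tc_experiment` the fit was run on, to overlay
#'   observed counts as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_catch <- function(object, genes = NULL, expt = NULL, ...) {
  m <- object$master
  if (is.null(genes)) {
    genes <- m$gene_id[order(m$gene_pvalue)][seq_len(min(6, nrow(m)))]
  }
  curves <- purrr::map_dfr(genes, function(g) {
    f <- object$fits[[g]]
    dplyr::mutate(predict(f), gene_id = g)
  })
  base <- m[match(genes, m$gene_id), c("gene_id", "mu_baseline", "ci_low", "ci_high")]
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$mu)) +
    ggplot2::geom_rect(data = base, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$ci_low, ymax = .data$ci_high),
                       fill = "grey85", alpha = 0.6) +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$mu_baseline),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "time", y = "fitted mean count",
                  title = "Fitted trajectories vs baseline fluctuation interval")
  if (!is.null(expt)) {
    obs <- purrr::map_dfr(genes, function(g) {
      tibble::tibble(gene_id = g, time = expt$metadata$time,
                     count = expt$counts[g, ])
    })
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(y = .data$count),
                                 size = 0.8, alpha = 0.6)
  }
  p
}

#' Write / read the master table
#'
#' CSV with the fixed column contract of [catch_trends()] (one row per gene,
#' floats at full precision); `read_master_table()` restores the tibble.
#'
#' @param tc A `trend_catch` object (or its master tibble).
#' @param path Output CSV path.
#' @return The path, invisibly (writer); the master tibble (reader).
#' @export
write_master_table <- function(tc, path) {
  master <- if (inherits(tc, "trend_catch")) tc$master else tibble::as_tibble(tc)
  readr::write_csv(master, path)
  invisible(path)
}

#' @rdname write_master_table
#' @export
read_master_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
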