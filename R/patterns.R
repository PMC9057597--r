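#' Find break points in a fitted trajectory
#'
#' A break point is an interior trend reversal along the sequence of
#' significant times: the baseline is prepended as the trajectory start
#' anchor at `mu_baseline`, the non-baseline times with per-time p-value
#' below `p_threshold` are connected in time order (non-significant times are
#' skipped), and an interior time whose fitted mean strictly exceeds both
#' neighbours is a peak (type I: up then down) while one strictly below both
#' neighbours is a trough (type II: down then up).  Ties with a neighbour
#' continue the previous direction and are never break points.
#'
#' @param times Non-baseline times (sorted) with fitted means `mu`.
#' @param mu Fitted means at `times`.
#' @param pvalues Per-time dynamic p-values at `times`.
#' @param baseline_time,mu_baseline Baseline anchor.
#' @param p_threshold Per-time significance threshold for a time to enter the
#'   connected sequence (default 0.05, on the raw per-time p).
#' @return Tibble with columns `time`, `kind` (`"peak"`/`"trough"`); zero
#'   rows when the significant sequence has fewer than 3 points.
#' @export
find_break_points <- function(times, mu, pvalues, baseline_time, mu_baseline,
                              p_threshold = 0.05) {
  stopifnot(length(times) == length(mu), length(mu) == length(pvalues))
  sig <- pvalues < p_threshold
  seq_t <- c(baseline_time, times[sig])
  seq_mu <- c(mu_baseline, mu[sig])
  out <- tibble::tibble(time = numeric(0), kind = character(0))
  n <- length(seq_t)
  if (n < 3) return(out)
  for (j in 2:(n - 1)) {
    if (seq_mu[j] > seq_mu[j - 1] && seq_mu[j] > seq_mu[j + 1]) {
      out <- tibble::add_row(out, time = seq_t[j], kind = "peak")
    } else if (seq_mu[j] < seq_mu[j - 1] && seq_mu[j] < seq_mu[j + 1]) {
      out <- tibble::add_row(out, time = seq_t[j], kind = "trough")
    }
  }
  out
}

#' Assign a trajectory pattern label
#'
#' Builds the master pattern (segment directions joined, e.g. `"up_down"`)
#' and the anchored sub-pattern (e.g. `"0D-2D up, 2D-14D down"`) from the
#' significant-time sequence and its break points.  Segments run between
#' consecutive anchors — the baseline start, each break point, and the last
#' significant time — and are labelled by the sign of the fitted-mean change.
#' A gene with no significant time is `"flat"`.
#'
#' @inheritParams find_break_points
#' @param time_unit_label Unit suffix for anchors in the sub-pattern, e.g.
#'   `"D"` (days), `"W"` (weeks); default `"D"`.
#' @return A list of class `tc_pattern`: `master_pattern`, `sub_pattern`,
#'   `break_points` (tibble as from [find_break_points()]).
#' @export
assign_pattern <- function(times, mu, pvalues, baseline_time, mu_baseline,
                           p_threshold = 0.05, time_unit_label = "D") {
  bp <- find_break_points(times, mu, pvalues, baseline_time, mu_baseline,
                          p_threshold)
  sig <- pvalues < p_threshold
  if (!any(sig)) {
    return(structure(list(master_pattern = "flat", sub_pattern = "flat",
                          break_points = bp), class = "tc_pattern"))
  }
  seq_t <- c(baseline_time, times[sig])
  seq_mu <- c(mu_baseline, mu[sig])
  anchors_t <- c(seq_t[1], bp$time, seq_t[length(seq_t)])
  anchors_mu <- seq_mu[match(anchors_t, seq_t)]
  dirs <- ifelse(diff(anchors_mu) >= 0, "up", "down")
  lab <- format_time(anchors_t)
  segs <- sprintf("%s%s-%s%s %s", lab[-length(lab)], time_unit_label,
                  lab[-1], time_unit_label, dirs)
  structure(list(
    master_pattern = paste(dirs, collapse = "_"),
    sub_pattern = paste(segs, collapse = ", "),
    break_points = bp
  ), class = "tc_pattern")
}

#' Trajectory pattern composition table
#'
#' Hierarchical counts of master patterns and sub-patterns, the tidy backing
#' table for a hierarchical pie / sunburst of trajectory composition.
#'
#' @param master A data frame with `master_pattern` and `sub_pattern` columns
#'   (rows are the genes to tally — pass the DDEG subset of the master table
#'   to summarise dynamic genes only).
#' @return Tibble `master_pattern`, `sub_pattern`, `n_genes`, sorted by
#'   descending count.
#' @export
pattern_composition <- function(master) {
  stopifnot(all(c("master_pattern", "sub_pattern") %in% names(master)))
  master |>
    dplyr::count(.data$master_pattern, .data$sub_pattern, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$master_pattern,
                   .data$sub_pattern)
}
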