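#' LOESS smoothing of pooled gene profiles
#'
#' Locally weighted (degree-1) regression of baseline-relative log2
#' fold-change on time over all points of one group — the pooled-pathway
#' smooth used for between-group trajectory comparison.  Deterministic given
#' the span.
#'
#' @param points Data frame with columns `time`, `log2fc` (one row per gene
#'   per time).
#' @param span LOESS span, default 0.75.
#' @return A `tc_loess` object; evaluate with `predict(fit, times)`.
#' @export
loess_curve <- function(points, span = 0.75) {
  stopifnot(all(c("time", "log2fc") %in% names(points)))
  n <- nrow(points)
  n_min <- 4
  if (n < n_min) stop("LOESS needs at least ", n_min, " points; got ", n)
  fit <- stats::loess(log2fc ~ time, data = points, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  structure(list(fit = fit, span = span,
                 range = range(points$time)), class = "tc_loess")
}

#' @export
predict.tc_loess <- function(object, newtimes, ...) {
  as.numeric(predict(object$fit, newdata = data.frame(time = newtimes)))
}

#' Area ratio between two smoothed curves on an interval
#'
#' `|integral(A - B)| / (|integral A| + |integral B| + eps)` over the
#' interval, integrals by the trapezoid rule on `n_nodes` points.  Symmetric
#' in the two curves, zero iff they coincide, bounded by ~1.  The raw
#' enclosed area `|integral(A - B)|` is available with
#' `normalize = FALSE`.
#'
#' @param curve_a,curve_b `tc_loess` fits (or any object with a `predict`
#'   method over time).
#' @param interval Length-2 numeric, `interval[1] < interval[2]`.
#' @param normalize Divide by the union-area normalizer (default `TRUE`).
#' @param n_nodes Trapezoid nodes per interval (default 5).
#' @param eps Normalizer guard, default 1e-9.
#' @return Non-negative scalar.
#' @export
area_ratio <- function(curve_a, curve_b, interval, normalize = TRUE,
                       n_nodes = 5, eps = 1e-9) {
  if (diff(interval) <= 0) stop("zero-length interval")
  x <- seq(interval[1], interval[2], length.out = n_nodes)
  a <- predict(curve_a, x)
  b <- predict(curve_b, x)
  num <- abs(trapz(x, a - b))
  if (!normalize) return(num)
  num / (abs(trapz(x, a)) + abs(trapz(x, b)) + eps)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Interval-wise permutation test for between-group trajectory differences
#'
#' Smooths each group's pooled gene profiles with LOESS, tiles the shared
#' time range into `n_bins` intervals, and computes the observed area ratio
#' between the two group curves in every interval.  The null distribution is
#' obtained by shuffling group labels at the gene level (a gene's whole
#' profile moves together, preserving within-gene autocorrelation) `n_perm`
#' times; the one-sided p per interval is
#' `(1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param profiles Long data frame: `gene_id`, `group` (exactly 2 levels),
#'   `time`, `log2fc`.
#' @param n_bins Number of intervals tiling the shared time range
#'   (default 100).
#' @param n_perm Label shuffles (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param span LOESS span (default 0.75).
#' @param normalize Area-ratio normalization, see [area_ratio()].
#' @return A tibble with one row per interval: `interval` (1-based index),
#'   `t_start`, `t_end`, `observed`, `pvalue`.
#' @export
permutation_test <- function(profiles, n_bins = 100, n_perm = 1000,
                             seed = 1, span = 0.75, normalize = TRUE) {
  stopifnot(all(c("gene_id", "group", "time", "log2fc") %in% names(profiles)))
  grps <- sort(unique(as.character(profiles$group)))
  if (length(grps) != 2) stop("exactly 2 groups required; got ", length(grps))
  gene_grp <- profiles |>
    dplyr::distinct(.data$gene_id, .data$group)
  if (anyDuplicated(gene_grp$gene_id)) {
    stop("a gene may belong to only one group")
  }
  n_per <- table(gene_grp$group)
  if (any(n_per < 2)) stop("need at least 2 genes per group")

  lo <- max(tapply(profiles$time, profiles$group, min))
  hi <- min(tapply(profiles$time, profiles$group, max))
  if (hi <= lo) stop("group time ranges do not overlap")
  edges <- seq(lo, hi, length.out = n_bins + 1)

  split_pts <- split(profiles[c("gene_id", "time", "log2fc")],
                     profiles$gene_id)
  genes <- names(split_pts)
  obs_grp <- gene_grp$group[match(genes, gene_grp$gene_id)]

  # one shared grid (4 sub-nodes per bin) so each statistic needs just two
  # LOESS evaluations; per-bin trapezoids are sliced out of the grid
  sub <- 4L
  grid <- seq(lo, hi, length.out = n_bins * sub + 1)
  bin_idx <- lapply(seq_len(n_bins), function(j) ((j - 1) * sub + 1):(j * sub + 1))
  stat_for <- function(assign) {
    pa <- dplyr::bind_rows(split_pts[assign == grps[1]])
    pb <- dplyr::bind_rows(split_pts[assign == grps[2]])
    ya <- predict(loess_curve(pa, span), grid)
    yb <- predict(loess_curve(pb, span), grid)
    vapply(bin_idx, function(ii) {
      x <- grid[ii]
      num <- abs(trapz(x, ya[ii] - yb[ii]))
      if (!normalize) num
      else num / (abs(trapz(x, ya[ii])) + abs(trapz(x, yb[ii])) + 1e-9)
    }, numeric(1))
  }

  observed <- stat_for(obs_grp)
  exceed <- integer(n_bins)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(n_perm)) {
    perm <- sample(obs_grp)
    exceed <- exceed + (stat_for(perm) >= observed)
  }
  tibble::tibble(
    interval = seq_len(n_bins),
    t_start = edges[-length(edges)],
    t_end = edges[-1],
    observed = observed,
    pvalue = (1 + exceed) / (n_perm + 1)
  )
}
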