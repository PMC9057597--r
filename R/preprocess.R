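#' Filter, normalize and batch-correct a time-course experiment
#'
#' Standard preprocessing ahead of trajectory modelling: genes of relatively
#' low abundance are removed, library sizes are equalized with relative log
#' expression (RLE, median-of-ratios) size factors, and — when requested and
#' more than one batch is present — batch effects are removed on the log2
#' scale with [limma::removeBatchEffect()] while preserving the time effects,
#' then back-transformed to pseudo-counts.
#'
#' Because the downstream model is a count model, normalized/corrected values
#' are rounded back to non-negative integers; the size factors used are
#' returned as an attribute `size_factors`.
#'
#' @param expt A [time_course_experiment()] object.
#' @param min_avg_count Keep genes whose mean raw count across samples is at
#'   least this value (default 1; 0 disables the filter).
#' @param normalize Apply RLE size-factor normalization (default `TRUE`).
#' @param batch_correct Remove batch effects (requires a `batch` metadata
#'   column with >1 level; otherwise a no-op with a message).
#' @return A `tc_experiment` with the filtered/adjusted counts.
#' @export
preprocess <- function(expt, min_avg_count = 1, normalize = TRUE,
                       batch_correct = FALSE) {
  stopifnot(inherits(expt, "tc_experiment"))
  counts <- expt$counts
  keep <- rowMeans(counts) >= min_avg_count
  if (!all(keep)) {
    message(sum(!keep), " / ", nrow(counts), " genes below abundance threshold removed")
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no genes left after abundance filtering")

  sf <- rep(1, ncol(counts))
  if (normalize && ncol(counts) >= 2) {
    sf <- rle_size_factors(counts)
    counts <- sweep(counts, 2, sf, "/")
  }

  if (batch_correct) {
    batch <- expt$metadata[["batch"]]
    if (is.null(batch) || length(unique(batch)) < 2) {
      message("single (or missing) batch: batch correction skipped")
    } else {
      design <- stats::model.matrix(~ factor(expt$metadata$time))
      lg <- limma::removeBatchEffect(log2(counts + 1), batch = factor(batch),
                                     design = design)
      counts <- pmax(2^lg - 1, 0)
    }
  }

  counts <- round(counts)
  out <- time_course_experiment(counts, expt$metadata, expt$baseline_time)
  attr(out, "size_factors") <- stats::setNames(sf, colnames(counts))
  out
}

#' RLE (median-of-ratios) size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples; genes with a zero geometric mean
#' (any zero count) are excluded from the median.  Factors are standardized
#' to geometric mean 1, which makes the normalization idempotent: factors
#' recomputed on normalized counts are exactly 1.
#'
#' @param counts Non-negative matrix, genes by samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
rle_size_factors <- function(counts) {
  lg <- log(counts)
  gm <- rowMeans(lg)                      # -Inf where any zero
  use <- is.finite(gm)
  if (!any(use)) stop("no gene has all-positive counts; cannot compute RLE factors")
  sf <- apply(lg[use, , drop = FALSE], 2, function(col) exp(median(col - gm[use])))
  sf / exp(mean(log(sf)))
}
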