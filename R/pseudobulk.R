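#' Pool single-cell counts into a cell-type pseudobulk library
#'
#' All cells of the requested type are grouped by sample and their counts
#' summed per gene, yielding a genes-by-samples integer matrix that can be
#' analysed like a bulk time course (feed the result to
#' [time_course_experiment()] via `pseudobulk_experiment()` or directly).
#'
#' @param counts Cells-by-genes count matrix (dense or `dgCMatrix`), cell
#'   ids as rownames, gene ids as colnames.
#' @param cells Data frame with columns `cell_id`, `cell_type`, `sample_id`
#'   (one row per cell).
#' @param samples Data frame with columns `sample_id`, `time` (numeric),
#'   optionally `replicate`.
#' @param cell_type The cell type to pool.
#' @return A `pseudobulk` object: `cell_type`, `counts` (genes x samples),
#'   `samples` (tibble incl. `n_cells`), and after [normalize_pseudobulk()]
#'   also `size_factors` and `norm_logcpm`.
#' @export
aggregate_pseudobulk <- function(counts, cells, samples, cell_type) {
  stopifnot(all(c("cell_id", "cell_type", "sample_id") %in% names(cells)),
            all(c("sample_id", "time") %in% names(samples)))
  if (!cell_type %in% cells$cell_type) {
    stop("unknown cell type: ", cell_type)
  }
  cells <- tibble::as_tibble(cells)
  samples <- tibble::as_tibble(samples)
  sel <- cells[cells$cell_type == cell_type, ]
  miss <- setdiff(sel$cell_id, rownames(counts))
  if (length(miss)) stop("cells missing from count matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  sub <- counts[sel$cell_id, , drop = FALSE]
  grp <- factor(sel$sample_id, levels = unique(sel$sample_id))
  # indicator crossprod handles dense and sparse input alike
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), nlevels(grp)))
  pooled <- as.matrix(Matrix::t(Matrix::crossprod(ind, sub)))  # genes x samples
  colnames(pooled) <- levels(grp)
  n_cells <- as.integer(table(grp)[levels(grp)])
  smp <- samples[match(levels(grp), samples$sample_id), ]
  if (anyNA(smp$sample_id)) stop("sample metadata missing for some samples")
  smp$n_cells <- n_cells
  structure(list(cell_type = cell_type, counts = pooled, samples = smp,
                 size_factors = NULL, norm_logcpm = NULL),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk> ", x$cell_type, ": ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (", sum(x$samples$n_cells), " cells)\n", sep = "")
  invisible(x)
}

#' Retain cell types with enough cells
#'
#' Pseudobulk libraries pooled from few cells are unreliable; this returns
#' the cell types whose cell count reaches `min_cells` under the chosen
#' scope — `"per-time"` (default) requires the threshold at every time
#' point, `"global"` over the whole data set.  The threshold is inclusive
#' (exactly `min_cells` cells is retained).
#'
#' @param cells,samples As in [aggregate_pseudobulk()].
#' @param min_cells Minimum cell count, default 1000.
#' @param scope `"per-time"` or `"global"`.
#' @return Character vector of retained cell types.
#' @export
filter_cell_types <- function(cells, samples, min_cells = 1000,
                              scope = c("per-time", "global")) {
  scope <- match.arg(scope)
  cells <- tibble::as_tibble(cells)
  cells$time <- samples$time[match(cells$sample_id, samples$sample_id)]
  if (scope == "global") {
    tab <- cells |> dplyr::count(.data$cell_type)
    return(sort(tab$cell_type[tab$n >= min_cells]))
  }
  times <- sort(unique(samples$time))
  tab <- cells |>
    dplyr::count(.data$cell_type, .data$time) |>
    tidyr::complete(cell_type = unique(cells$cell_type),
                    time = times, fill = list(n = 0L)) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(min_n = min(.data$n))
  sort(tab$cell_type[tab$min_n >= min_cells])
}

#' Remove lowly expressed genes from a pseudobulk library
#'
#' Keeps genes with counts-per-million at least `min_cpm` in at least
#' `min_samples` samples (the CPM-in-k-samples rule; `min_samples` defaults
#' to the size of the smallest time group, so a gene expressed in one full
#' time point survives).
#'
#' @param lib A `pseudobulk` object.
#' @param min_cpm CPM threshold, default 1.
#' @param min_samples Number of samples that must pass (default: smallest
#'   time-group size).
#' @return The filtered `pseudobulk` object.
#' @export
filter_low_expression <- function(lib, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(lib, "pseudobulk"))
  if (is.null(min_samples)) {
    min_samples <- min(table(lib$samples$time))
  }
  libsize <- colSums(lib$counts)
  if (any(libsize == 0)) stop("sample(s) with all-zero counts: ",
                              paste(colnames(lib$counts)[libsize == 0], collapse = ", "))
  cpm <- sweep(lib$counts, 2, libsize, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) {
    stop("all genes filtered; lower `min_cpm` (", min_cpm,
         ") or `min_samples` (", min_samples, ")")
  }
  lib$counts <- lib$counts[keep, , drop = FALSE]
  lib$norm_logcpm <- NULL
  lib$size_factors <- NULL
  lib
}

#' RLE-normalize a pseudobulk library
#'
#' Computes relative log expression size factors (median over genes of the
#' sample count over the gene's geometric mean across samples, genes with a
#' zero geometric mean excluded), scales counts by them, and stores
#' `norm_logcpm = log2(CPM + 1)` computed on the scaled counts.
#'
#' @param lib A `pseudobulk` object (>= 2 samples).
#' @return The library with `size_factors` and `norm_logcpm` filled.
#' @export
normalize_pseudobulk <- function(lib) {
  stopifnot(inherits(lib, "pseudobulk"))
  if (ncol(lib$counts) < 2) stop("normalization needs >= 2 samples")
  if (any(colSums(lib$counts) == 0)) stop("sample with all-zero counts")
  sf <- rle_size_factors(lib$counts)
  norm <- sweep(lib$counts, 2, sf, "/")
  eff_lib <- colSums(norm)
  cpm <- sweep(norm, 2, eff_lib, "/") * 1e6
  lib$size_factors <- sf
  lib$effective_library <- eff_lib
  lib$norm_logcpm <- log2(cpm + 1)
  lib
}

#' Convert a pseudobulk library to a time-course experiment
#'
#' @param lib A `pseudobulk` object.
#' @param baseline_time Baseline time value.
#' @return A [time_course_experiment()] on the pooled counts.
#' @export
pseudobulk_experiment <- function(lib, baseline_time) {
  stopifnot(inherits(lib, "pseudobulk"))
  meta <- lib$samples
  if (is.null(meta[["replicate"]])) {
    meta$replicate <- stats::ave(seq_len(nrow(meta)), meta$time, FUN = seq_along)
  }
  time_course_experiment(round(lib$counts), meta, baseline_time)
}
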