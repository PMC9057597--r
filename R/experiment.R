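#' Assemble a time-course count experiment
#'
#' Bundles a raw gene-by-sample count matrix with per-sample time, replicate
#' and (optionally) batch annotation, plus the user-defined baseline time
#' (e.g. `0` for "0 hour" controls).  All downstream modelling — baseline
#' fluctuation interval, trajectory spline, dynamic p-values — starts from
#' this object.
#'
#' @param counts Non-negative integer matrix, genes in rows (unique rownames),
#'   samples in columns, or a data frame whose first column is the gene id.
#' @param metadata Data frame with columns `sample_id`, `time` (numeric),
#'   `replicate`, and optionally `batch`.  Every column of `counts` must have
#'   a metadata row.
#' @param baseline_time One of the observed time values; samples at this time
#'   define the baseline fluctuation interval.
#'
#' @return An object of class `tc_experiment`: a list with `counts` (integer
#'   matrix), `metadata` (tibble, ordered as the count columns) and
#'   `baseline_time`.
#' @examples
#' counts <- matrix(rpois(12, 20), 2, 6,
#'   dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' meta <- data.frame(sample_id = paste0("s", 1:6),
#'   time = rep(c(0, 1, 2), each = 2), replicate = rep(1:2, 3))
#' expt <- time_course_experiment(counts, meta, baseline_time = 0)
#' @export
time_course_experiment <- function(counts, metadata, baseline_time) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("`counts` must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    idx <- arrayInd(head(bad, 5), dim(counts))
    stop("counts must be non-negative integers; offending cells (gene, sample): ",
         paste(sprintf("(%s, %s)", rownames(counts)[idx[, 1]], colnames(counts)[idx[, 2]]),
               collapse = ", "))
  }
  storage.mode(counts) <- "double"

  metadata <- tibble::as_tibble(metadata)
  req <- c("sample_id", "time", "replicate")
  if (!all(req %in% names(metadata))) {
    stop("metadata needs columns: ", paste(setdiff(req, names(metadata)), collapse = ", "))
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$time <- as.numeric(metadata$time)
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (!baseline_time %in% metadata$time) {
    stop("baseline_time ", baseline_time, " not among observed times: ",
         paste(sort(unique(metadata$time)), collapse = ", "))
  }
  structure(
    list(counts = counts, metadata = metadata, baseline_time = as.numeric(baseline_time)),
    class = "tc_experiment"
  )
}

#' @export
print.tc_experiment <- function(x, ...) {
  tms <- sort(unique(x$metadata$time))
  cat("<tc_experiment> ", nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  cat("  times: ", paste(format_time(tms), collapse = ", "),
      " (baseline ", format_time(x$baseline_time), ")\n", sep = "")
  if (!is.null(x$metadata$batch)) {
    cat("  batches: ", paste(unique(x$metadata$batch), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a count table plus sample metadata into a `tc_experiment`
#'
#' Supports a delimited gene-by-sample table (CSV/TSV, genes in the first
#' column, header of sample ids) or a MatrixMarket triplet (`.mtx` with
#' sidecar gene and sample name files, one name per line).
#'
#' @param counts_path Path to the counts file.
#' @param metadata_path CSV with columns `sample_id`, `time`, `replicate`,
#'   optionally `batch`.
#' @param baseline_time Baseline time value (see [time_course_experiment()]).
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param genes_path,samples_path Sidecar name files, required for
#'   `format = "mtx"`.
#' @return A [time_course_experiment()] object.
#' @export
read_counts <- function(counts_path, metadata_path, baseline_time,
                        format = c("auto", "csv", "tsv", "mtx"),
                        genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(counts_path)),
                     mtx = "mtx", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(samples_path)) {
      stop("MTX input needs `genes_path` and `samples_path` sidecar files")
    }
    m <- as.matrix(Matrix::readMM(counts_path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
    counts <- m
  } else {
    delim <- if (format == "tsv") "\t" else ","
    df <- readr::read_delim(counts_path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    counts <- df
  }
  metadata <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  time_course_experiment(counts, metadata, baseline_time)
}

#' Write a count table and metadata to disk
#'
#' Inverse of [read_counts()] for the delimited format; round-trips a
#' `tc_experiment` exactly.
#'
#' @param expt A `tc_experiment`.
#' @param counts_path,metadata_path Output CSV paths.
#' @return `expt`, invisibly.
#' @export
write_counts <- function(expt, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(expt$counts), expt$counts,
                   check.names = FALSE)
  readr::write_csv(tibble::as_tibble(df), counts_path)
  readr::write_csv(expt$metadata, metadata_path)
  invisible(expt)
}

# distinct sorted times, baseline first element dropped on request
expt_times <- function(expt, include_baseline = TRUE) {
  tms <- sort(unique(expt$metadata$time))
  if (!include_baseline) tms <- setdiff(tms, expt$baseline_time)
  tms
}
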