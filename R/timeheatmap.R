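#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' gene ids.  Parsing is delegated to [fgsea::gmtPathways()]; duplicate genes
#' within a set are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT: ", path)
  lapply(sets, unique)
}

#' Up/down DDEG sets per time window
#'
#' Slides over consecutive observed-time windows `[t_{j-1}, t_j]` (starting
#' at the baseline) and collects, per window, the DDEGs whose fitted-mean
#' log2 change across the window exceeds `delta_log2` (up) or falls below
#' `-delta_log2` (down).  Changes use `log2(mu + 1)` so near-zero means stay
#' bounded.  A gene can change direction between windows but is never in
#' both directions within one window.
#'
#' @param tc A `trend_catch` from [catch_trends()].
#' @param delta_log2 Direction threshold per window in log2 units
#'   (default 0.25).
#' @param genes Gene ids to consider (default: the DDEGs).
#' @return Tibble `t_start`, `t_end`, `window` (label), `direction`
#'   (`"up"`/`"down"`), `gene_id`, `delta` (signed log2 change).
#' @export
window_gene_sets <- function(tc, delta_log2 = 0.25, genes = NULL) {
  stopifnot(inherits(tc, "trend_catch"))
  if (is.null(genes)) genes <- tc$master$gene_id[tc$master$is_ddeg]
  wd <- window_deltas(tc, genes)
  dplyr::filter(wd, abs(.data$delta) > delta_log2) |>
    dplyr::mutate(direction = ifelse(.data$delta > 0, "up", "down")) |>
    dplyr::select("t_start", "t_end", "window", "direction", "gene_id", "delta")
}

# per-gene signed log2(mu+1) change across every consecutive window
# (baseline anchor prepended); no threshold applied
window_deltas <- function(tc, genes) {
  all_t <- c(tc$baseline_time, tc$times)
  if (length(genes) == 0 || length(all_t) < 2) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          window = character(0), gene_id = character(0),
                          delta = numeric(0)))
  }
  mu_b <- tc$master$mu_baseline[match(genes, tc$master$gene_id)]
  lmu <- matrix(0, length(genes), length(all_t))
  for (i in seq_along(genes)) {
    f <- tc$fits[[genes[i]]]
    lmu[i, ] <- log2(c(mu_b[i], f$fitted_mu) + 1)
  }
  unit <- tc$params$time_unit_label
  purrr::map_dfr(seq_len(length(all_t) - 1), function(j) {
    tibble::tibble(
      t_start = all_t[j], t_end = all_t[j + 1],
      window = paste0(format_time(all_t[j]), unit, "-",
                      format_time(all_t[j + 1]), unit),
      gene_id = genes, delta = lmu[, j + 1] - lmu[, j]
    )
  })
}

#' One-sided Fisher-exact enrichment of a window gene list in gene sets
#'
#' For each set, tests over-representation of the window's directional gene
#' list against the universe with the one-sided (greater) Fisher exact test
#' on the 2x2 table (in set vs not) x (in list vs not).
#'
#' @param list_genes Character vector of genes in the window/direction list.
#' @param sets Named list of gene sets (e.g. [read_gmt()]).
#' @param universe All genes the analysis could have selected from (must
#'   contain `list_genes`).
#' @return Tibble `set`, `n_overlap`, `n_list`, `n_set`, `pvalue`.
#' @export
enrich_window <- function(list_genes, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  list_genes <- intersect(unique(list_genes), universe)
  purrr::imap_dfr(sets, function(gs, nm) {
    gs <- intersect(gs, universe)
    a <- length(intersect(gs, list_genes))
    b <- length(list_genes) - a
    c_ <- length(gs) - a
    d <- length(universe) - a - b - c_
    p <- if (a == 0) 1 else
      fisher.test(matrix(c(a, b, c_, d), 2, 2), alternative = "greater")$p.value
    tibble::tibble(set = nm, n_overlap = a, n_list = length(list_genes),
                   n_set = length(gs), pvalue = p)
  })
}

#' Build the TimeHeatmap table
#'
#' Pathway-by-window summary of dynamic change: for every window the up and
#' down DDEG lists are tested for enrichment in each gene set
#' ([enrich_window()]); the union of every window's `top_k` most enriched
#' sets (smallest enrichment p in either direction) forms the rows.  Each
#' cell holds `Avg_log2FC` — the mean, over that pathway's DDEGs that moved
#' in the window, of their signed per-window log2 change (0 when none moved)
#' — and each row is annotated with `n_ddeg` (pathway DDEGs anywhere in the
#' course), `pct_go` (100 * n_ddeg / pathway size in the collection) and
#' `go_mean_logfc`, the row-sum of `Avg_log2FC` (the accumulated course-long
#' change used to rank pathways).
#'
#' @param tc A `trend_catch`.
#' @param sets Named list of gene sets ([read_gmt()]).
#' @param universe Enrichment universe (default: all genes in the master
#'   table, i.e. genes surviving preprocessing).
#' @param top_k Sets kept per window by enrichment p (default 10).
#' @param delta_log2 Window membership threshold, see [window_gene_sets()].
#' @param window_members Averaging scope for `Avg_log2FC`:
#'   `"window"` (default) averages the pathway DDEGs that moved in that
#'   window; `"all"` averages all the pathway's DDEGs' deltas in every
#'   window.
#' @return A `timeheatmap` object: `table` (long tibble: `set`, `window`,
#'   `t_start`, `t_end`, `avg_log2fc`, `n_genes`, `enrich_p_up`,
#'   `enrich_p_down`), `summary` (per-set `n_ddeg`, `pct_go`,
#'   `go_mean_logfc`, ordered by `abs(go_mean_logfc)` descending),
#'   `windows`.  `tidy()` returns the long table.
#' @export
build_timeheatmap <- function(tc, sets, universe = NULL, top_k = 10,
                              delta_log2 = 0.25,
                              window_members = c("window", "all")) {
  stopifnot(inherits(tc, "trend_catch"))
  window_members <- match.arg(window_members)
  if (length(sets) == 0) stop("empty gene-set collection")
  if (is.null(universe)) universe <- tc$master$gene_id
  ddegs <- tc$master$gene_id[tc$master$is_ddeg]
  ws <- window_gene_sets(tc, delta_log2 = delta_log2)
  all_t <- c(tc$baseline_time, tc$times)
  unit <- tc$params$time_unit_label
  windows <- tibble::tibble(
    t_start = all_t[-length(all_t)], t_end = all_t[-1],
    window = paste0(format_time(all_t[-length(all_t)]), unit, "-",
                    format_time(all_t[-1]), unit))

  enr <- purrr::map_dfr(seq_len(nrow(windows)), function(j) {
    w <- windows$window[j]
    up <- ws$gene_id[ws$window == w & ws$direction == "up"]
    dn <- ws$gene_id[ws$window == w & ws$direction == "down"]
    dplyr::bind_rows(
      dplyr::mutate(enrich_window(up, sets, universe), direction = "up"),
      dplyr::mutate(enrich_window(dn, sets, universe), direction = "down")
    ) |> dplyr::mutate(window = w)
  })
  enr$pvalue_adj <- p.adjust(enr$pvalue, method = "holm")

  top_sets <- enr |>
    dplyr::group_by(.data$window, .data$set) |>
    dplyr::summarise(p_best = min(.data$pvalue), .groups = "drop_last") |>
    dplyr::slice_min(.data$p_best, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$set) |>
    dplyr::pull()

  wd_all <- window_deltas(tc, ddegs)
  cells <- purrr::map_dfr(top_sets, function(s) {
    purrr::map_dfr(seq_len(nrow(windows)), function(j) {
      w <- windows$window[j]
      vals <- if (window_members == "window") {
        ws$delta[ws$window == w & ws$gene_id %in% sets[[s]]]
      } else {
        wd_all$delta[wd_all$window == w & wd_all$gene_id %in% sets[[s]]]
      }
      tibble::tibble(set = s, window = w,
                     t_start = windows$t_start[j], t_end = windows$t_end[j],
                     avg_log2fc = if (length(vals)) mean(vals) else 0,
                     n_genes = length(vals))
    })
  })
  cells <- cells |>
    dplyr::left_join(
      enr |>
        dplyr::select("set", "window", "direction", "pvalue") |>
        tidyr::pivot_wider(names_from = "direction", values_from = "pvalue",
                           names_prefix = "enrich_p_"),
      by = c("set", "window"))

  summary <- cells |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(go_mean_logfc = sum(.data$avg_log2fc), .groups = "drop") |>
    dplyr::mutate(
      n_ddeg = vapply(.data$set, function(s) length(intersect(sets[[s]], ddegs)),
                      integer(1), USE.NAMES = FALSE),
      set_size = vapply(.data$set, function(s) length(sets[[s]]), integer(1),
                        USE.NAMES = FALSE),
      pct_go = 100 * .data$n_ddeg / .data$set_size
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$go_mean_logfc)), .data$set)

  structure(list(table = cells, summary = summary, windows = windows,
                 params = list(top_k = top_k, delta_log2 = delta_log2,
                               window_members = window_members)),
            class = "timeheatmap")
}

#' @export
print.timeheatmap <- function(x, ...) {
  cat("<timeheatmap> ", nrow(x$summary), " pathways x ", nrow(x$windows),
      " windows\n", sep = "")
  print(head(x$summary, 5))
  invisible(x)
}

#' @describeIn build_timeheatmap Long pathway-by-window table.
#' @param x A `timeheatmap`.
#' @param ... Unused.
#' @export
tidy.timeheatmap <- function(x, ...) x$table

#' Two-sided pathway ranking by accumulated log2 fold change
#'
#' The `n_top` most positively and most negatively changed pathways by
#' `go_mean_logfc` (ties broken alphabetically by pathway name), the tidy
#' backing table for the two-sided bar plot.
#'
#' @param th A `timeheatmap` from [build_timeheatmap()].
#' @param n_top Pathways per side (default 5).
#' @return Tibble `set`, `go_mean_logfc`, `side` (`"positive"`/`"negative"`).
#' @export
two_sided_bar <- function(th, n_top = 5) {
  stopifnot(inherits(th, "timeheatmap"))
  s <- dplyr::arrange(th$summary, dplyr::desc(.data$go_mean_logfc), .data$set)
  pos <- s |> dplyr::filter(.data$go_mean_logfc > 0) |> head(n_top) |>
    dplyr::mutate(side = "positive")
  neg <- dplyr::arrange(th$summary, .data$go_mean_logfc, .data$set) |>
    dplyr::filter(.data$go_mean_logfc < 0) |> head(n_top) |>
    dplyr::mutate(side = "negative")
  dplyr::bind_rows(pos, neg) |>
    dplyr::select("set", "go_mean_logfc", "side")
}

#' @describeIn build_timeheatmap Heatmap of Avg_log2FC per pathway per
#'   window (tile plot ordered by `go_mean_logfc`).
#' @param object A `timeheatmap`.
#' @export
autoplot.timeheatmap <- function(object, ...) {
  lv <- rev(object$summary$set)
  df <- dplyr::mutate(object$table,
                      set = factor(.data$set, levels = lv),
                      window = factor(.data$window,
                                      levels = object$windows$window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$set,
                                   fill = .data$avg_log2fc)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$avg_log2fc)),
                       size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "Avg_log2FC") +
    ggplot2::labs(x = "time window", y = NULL,
                  title = "Pathway trajectory TimeHeatmap")
}

#' Export a TimeHeatmap to CSV
#'
#' Writes the long pathway-by-window table and the per-pathway summary.
#'
#' @param th A `timeheatmap`.
#' @param table_path,summary_path Output CSV paths.
#' @return `th`, invisibly.
#' @export
write_timeheatmap <- function(th, table_path, summary_path) {
  readr::write_csv(th$table, table_path)
  readr::write_csv(th$summary, summary_path)
  invisible(th)
}
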