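# Diagnostic plots for pipeline outputs: DEG set bars, pair scatter with
# cluster labels, module time courses with replicate bands, clustered
# heatmaps. Each plot's numeric series is available from a companion
# function so tests assert on numbers, not pixels.

#' Bar chart of DEG counts per time point and intersection pattern
#'
#' UpSet-style summary: total and time-point-unique DEG counts per time
#' point, plus the cardinality of each exact intersection pattern.
#'
#' @param de Differential-expression results ([run_de()]).
#' @return A ggplot object; the plotted series is in attribute `"series"`.
#' @export
plot_deg_counts <- function(de) {
  sets <- deg_sets(de)
  series <- dplyr::bind_rows(
    dplyr::transmute(sets$unique_counts,
                     time_h = factor(.data$time_h),
                     kind = "total", n = .data$n_total),
    dplyr::transmute(sets$unique_counts,
                     time_h = factor(.data$time_h),
                     kind = "unique to time point", n = .data$n_unique)
  )
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_h, y = .data$n,
                                    fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "time (h post-inoculation)", y = "DEGs",
                  fill = NULL) +
    ggplot2::theme_minimal()
  attr(p, "series") <- series
  p
}

#' Scatter plot of one gene pair
#'
#' Log2 expression of two genes across all samples, colored by condition;
#' when a pair clustering is supplied, point shape shows the GMM sample
#' cluster.
#'
#' @param gem A `nodnet_gem`.
#' @param gene_i,gene_j Gene ids.
#' @param clustering Optional [pair_gmm()] result for the pair.
#' @return A ggplot object with the series in attribute `"series"`.
#' @export
plot_pair_scatter <- function(gem, gene_i, gene_j, clustering = NULL) {
  stopifnot(inherits(gem, "nodnet_gem"))
  series <- tibble::tibble(
    sample = colnames(gem$values),
    x = unname(gem$values[gene_i, ]),
    y = unname(gem$values[gene_j, ]),
    condition = gem$sample_meta$condition,
    cluster = if (is.null(clustering)) NA_integer_ else clustering$labels
  )
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$condition)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = gene_i, y = gene_j) +
    ggplot2::theme_minimal()
  if (!is.null(clustering)) {
    p <- p + ggplot2::aes(shape = factor(.data$cluster))
  }
  attr(p, "series") <- series
  p
}

#' Per-condition time-course series for a module
#'
#' For each gene, condition and time point: the replicate mean and a 68%
#' band (mean +/- one standard error of the mean across replicates).
#'
#' @param gem A `nodnet_gem`.
#' @param genes Character vector of module gene ids.
#' @return Tibble: `gene`, `condition`, `time_h`, `mean`, `sem`, `lo`,
#'   `hi`.
#' @export
module_timecourse_series <- function(gem, genes) {
  stopifnot(inherits(gem, "nodnet_gem"))
  genes <- intersect(genes, rownames(gem$values))
  long <- tibble::as_tibble(gem$values[genes, , drop = FALSE],
                            rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::left_join(gem$sample_meta, by = "sample")
  long |>
    dplyr::group_by(.data$gene, .data$condition, .data$time_h) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    ) |>
    dplyr::mutate(lo = .data$mean - .data$sem, hi = .data$mean + .data$sem)
}

#' Module time-course plot
#'
#' One panel per gene: per-condition mean log2 expression over time with a
#' 68% confidence band (one SEM across the biological replicates).
#'
#' @inheritParams module_timecourse_series
#' @return A ggplot object with the series in attribute `"series"`.
#' @export
plot_module_timecourse <- function(gem, genes) {
  series <- module_timecourse_series(gem, genes)
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_h, y = .data$mean,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "time (h post-inoculation)",
                  y = "log2 expression") +
    ggplot2::theme_minimal()
  attr(p, "series") <- series
  p
}

#' Sample linkage for a clustered heatmap
#'
#' Average-linkage hierarchical clustering of samples on Euclidean distance
#' over the selected genes; the numeric linkage (hclust merge matrix and
#' heights) is returned so it can be tested directly.
#'
#' @param gem A `nodnet_gem`.
#' @param genes Gene ids to cluster on (default: all).
#' @return An `hclust` object over samples.
#' @export
heatmap_linkage <- function(gem, genes = rownames(gem$values)) {
  v <- gem$values[intersect(genes, rownames(gem$values)), , drop = FALSE]
  stats::hclust(stats::dist(t(v), method = "euclidean"), method = "average")
}

#' Clustered expression heatmap
#'
#' Tile heatmap of log2 expression with samples ordered by average-linkage
#' Euclidean clustering ([heatmap_linkage()]).
#'
#' @inheritParams heatmap_linkage
#' @return A ggplot object; the sample order is in attribute
#'   `"sample_order"` and the linkage in attribute `"linkage"`.
#' @export
plot_module_heatmap <- function(gem, genes = rownames(gem$values)) {
  genes <- intersect(genes, rownames(gem$values))
  hc <- heatmap_linkage(gem, genes)
  ord <- hc$labels[hc$order]
  long <- tibble::as_tibble(gem$values[genes, , drop = FALSE],
                            rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::mutate(sample = factor(.data$sample, levels = ord))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$sample, y = .data$gene,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  attr(p, "sample_order") <- ord
  attr(p, "linkage") <- hc
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a threshold object draws the chi-square trace of the RMT
#' sweep; on a DE result, a volcano plot; on a modules object, the module
#' size distribution.
#'
#' @param object A `nodnet_threshold`, `nodnet_de` or `nodnet_modules`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-nodnet
NULL

#' @rdname autoplot-nodnet
#' @exportS3Method ggplot2::autoplot
autoplot.nodnet_threshold <- function(object, ...) {
  tr <- dplyr::filter(object$trace, !is.na(.data$chi2))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cutoff, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$decision)) +
    ggplot2::geom_hline(yintercept = object$chi2_critical,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dotted") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "correlation cutoff", y = "chi-square vs Poisson NNSD",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nodnet
#' @exportS3Method ggplot2::autoplot
autoplot.nodnet_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~time_h) +
    ggplot2::labs(x = "log2 fold change (inoculated / control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-nodnet
#' @exportS3Method ggplot2::autoplot
autoplot.nodnet_modules <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n_genes)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::labs(x = "genes per module", y = "modules") +
    ggplot2::theme_minimal()
}
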