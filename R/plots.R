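# ggplot2 views of the survey's result types.

#' Ranked pan-cancer co-expression curve
#'
#' Genes ranked by median z-score (x) against the median z (y), with optional
#' highlighted genes labelled — the standard view of a co-expression survey.
#'
#' @param scores A [pan_cancer_median()] tibble.
#' @param highlight Character vector of genes to emphasize.
#' @return A ggplot object.
#' @export
plot_coexpression_rank <- function(scores, highlight = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$rank, y = .data$median_z)) +
    ggplot2::geom_point(size = 0.4, color = "grey40") +
    ggplot2::labs(x = "gene rank", y = "median z-score") +
    ggplot2::theme_classic()
  if (!is.null(highlight)) {
    hi <- dplyr::filter(scores, .data$gene %in% highlight)
    p <- p +
      ggplot2::geom_point(data = hi, color = "firebrick", size = 1.5) +
      ggplot2::geom_text(data = hi, ggplot2::aes(label = .data$gene),
                         vjust = -0.6, size = 3)
  }
  p
}

#' @rdname plot_coexpression_rank
#' @param object,... Autoplot arguments.
#' @export
autoplot.pan_cancer_score <- function(object, ...) {
  plot_coexpression_rank(object, ...)
}

#' Signed significance track of the chromatin scan
#'
#' Per-bin `sign(rho) * -log10(padj)` along the window; positive correlates
#' point up, negative correlates are inverted below the axis.
#'
#' @param track A `bin_track` from [correlate_bins()].
#' @param alpha Threshold drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_bin_track <- function(track, alpha = 1e-4) {
  d <- dplyr::filter(tibble::as_tibble(unclass(track)), !is.na(.data$rho))
  cut <- -log10(alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$score,
                                  color = .data$score > 0)) +
    ggplot2::geom_segment(ggplot2::aes(xend = (.data$start + .data$end) / 2,
                                       yend = 0), linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-cut, cut), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c("FALSE" = "steelblue",
                                           "TRUE" = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = sprintf("position on %s (bp)", d$chrom[1]),
                  y = expression(sign(rho) %*% -log[10](p[adj]))) +
    ggplot2::theme_classic()
}

#' @rdname plot_bin_track
#' @param object,... Autoplot arguments.
#' @export
autoplot.bin_track <- function(object, ...) plot_bin_track(object, ...)

#' Factor enrichment scatter
#'
#' Enrichment score (`log2(obs/exp) * -log10(padj)`) against the permutation
#' z-score, one point per factor, top factors labelled.
#'
#' @param enrichment A `factor_enrichment` tibble.
#' @param label_top Number of top-scoring factors to label.
#' @return A ggplot object.
#' @export
plot_factor_enrichment <- function(enrichment, label_top = 5) {
  d <- tibble::as_tibble(unclass(enrichment))
  top <- utils::head(dplyr::arrange(d, dplyr::desc(.data$score)), label_top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$score)) +
    ggplot2::geom_point(color = "grey40") +
    ggplot2::geom_point(data = top, color = "firebrick") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$factor),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "standard deviations beyond expectation (z)",
                  y = expression(log[2](obs / exp) %*% -log[10](p[adj]))) +
    ggplot2::theme_classic()
}

#' @rdname plot_factor_enrichment
#' @param object,... Autoplot arguments.
#' @export
autoplot.factor_enrichment <- function(object, ...) {
  plot_factor_enrichment(object, ...)
}

#' Median z-score by regulatory-distance bin
#'
#' Boxplots of the pan-cancer median z per fixed-size distance bin, the view
#' that couples regulatory similarity to co-expression.
#'
#' @param dist_scores Result of [gene_distance()] joined to a
#'   [pan_cancer_median()] table (columns `dist_bin`, `median_z`).
#' @param max_bins Number of closest bins shown.
#' @return A ggplot object.
#' @export
plot_distance_bins <- function(dist_scores, max_bins = 25) {
  d <- dplyr::filter(dist_scores, .data$dist_bin <= max_bins,
                     !is.na(.data$median_z))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$dist_bin),
                                  y = .data$median_z)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = "distance bin (closest genes first)",
                  y = "median z-score") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
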