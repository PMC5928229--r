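#' Quadrant scatter of MFP versus lung enrichment
#'
#' The screen's summary view: each gene's representation in MFP tumours
#' relative to the reference pellet (x, log scale) against its enrichment
#' in lungs relative to MFP tumours (y, log scale), with the
#' empirical-control cutoff drawn on the lung axis and the quadrant
#' thresholds as dashed lines.
#'
#' @param hits Scored hit tibble from [call_hits()] (or a `met_screen`).
#' @param cutoff Lung-axis cutoff; defaults to the table's `cutoff`
#'   attribute.
#' @param mfp_threshold MFP-axis threshold.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(hits, cutoff = NULL, mfp_threshold = 1) {
  if (inherits(hits, "met_screen")) hits <- hits$hits
  cutoff <- cutoff %||% attr(hits, "cutoff") %||% 5
  df <- filter(hits, .data$included)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_fc_mfp,
                                   y = .data$mean_lung_vs_mfp)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = mfp_threshold, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role,
                                     shape = .data$is_hit), alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "MFP vs reference (fold change)",
                  y = "Lung vs MFP (enrichment score)",
                  colour = "role", shape = "hit") +
    ggplot2::theme_minimal()
}

#' Ranked hit bar plot
#'
#' Hits in descending order of lung enrichment, with the applied cutoff as
#' a dotted line.
#'
#' @inheritParams plot_quadrants
#' @param top Number of top-ranked hits to show.
#' @return A ggplot object.
#' @export
plot_hit_ranks <- function(hits, cutoff = NULL, top = 50L) {
  if (inherits(hits, "met_screen")) hits <- hits$hits
  cutoff <- cutoff %||% attr(hits, "cutoff") %||% 5
  df <- hits %>%
    filter(.data$is_hit) %>%
    arrange(.data$rank) %>%
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_symbol, -.data$mean_lung_vs_mfp),
    y = .data$mean_lung_vs_mfp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "Lung vs MFP (enrichment score)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Autoplot method for screen runs
#'
#' @param object A `met_screen` object.
#' @param type `"quadrants"` or `"ranks"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.met_screen <- function(object, type = c("quadrants", "ranks"), ...) {
  type <- match.arg(type)
  switch(type,
         quadrants = plot_quadrants(object, ...),
         ranks = plot_hit_ranks(object, ...))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
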