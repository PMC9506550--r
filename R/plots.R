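# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA score plot
#'
#' @param object A `dam_pca` from [ft_pca()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2, coloured by organ, shaped by line.
#' @method autoplot dam_pca
#' @export
autoplot.dam_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$organ,
                               shape = .data$line)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      title = "Global metabolite profile PCA"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style DAM plot for one organ
#'
#' @param result A `dam_result` from [dam_analysis()].
#' @param organ Organ to display (default "leaf").
#' @return A ggplot of log2 fold change vs -log10 p, DAMs highlighted.
#' @export
plot_dam_volcano <- function(result, organ = "leaf") {
  d <- tidy(result)
  d <- d[d$organ == organ, ]
  d$p <- pmin(d$p_line, d$p_interaction)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p),
                                  colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * d$min_abs_log2_fc[1],
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(d$p_max[1]), linetype = 2) +
    ggplot2::scale_colour_manual(values = c("grey60", "firebrick"),
                                 name = "DAM") +
    ggplot2::labs(x = "log2 FC (Bd3-1 / Bd21)", y = "-log10 p",
                  title = paste("Differential accumulation:", organ)) +
    ggplot2::theme_minimal()
}

#' Pathway enrichment bubble plot
#'
#' @param object An `enrichment` tibble from [enrich_pathways()].
#' @param ... Unused.
#' @return A ggplot: impact vs -log10 FDR, bubble size = hits.
#' @method autoplot enrichment
#' @export
autoplot.enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$impact, -log10(.data$fdr),
                               size = .data$hits,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$pathway), size = 2.6,
                       vjust = -1, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey50", "firebrick"),
                                 name = "selected") +
    ggplot2::labs(x = "pathway impact", y = "-log10 FDR",
                  title = "Pathway enrichment") +
    ggplot2::theme_minimal()
}
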