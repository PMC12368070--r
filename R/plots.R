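#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metagene profile with its bootstrap confidence band
#'
#' @param object A `metagene_profile` tibble from [bootstrap_mean_ci()].
#' @param ... Ignored.
#' @return A ggplot: line for the mean, ribbon for the confidence band,
#'   shaded gene-body region when position regions are present.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean))
  if ("region" %in% names(object)) {
    body <- range(object$position[object$region == "body"])
    p <- p + ggplot2::annotate("rect", xmin = body[1], xmax = body[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "metagene position (flank | scaled body | flank)",
                  y = "bootstrapped mean log2 coverage") +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-gene velocity or aligned-change matrix
#'
#' Genes are ordered by body length; NA bins (no mNET-seq signal, or masked
#' outside the gene body) are gray; for TSS-anchored matrices the gene-end
#' bin is traced as a black line.
#'
#' @param object A `velocity_matrix` or `aligned_matrix` tibble.
#' @param value Column to fill by (default `"ratio"` for velocity matrices,
#'   `"change"`/`"value"` for aligned matrices).
#' @param ... Ignored.
#' @return A ggplot raster heatmap.
#' @export
autoplot.velocity_matrix <- function(object, value = NULL, ...) {
  value <- value %||% intersect(c("ratio", "change", "value"), names(object))[1]
  ord <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$gene_id),
                          nb = max(.data$bin_index), .groups = "drop")
  ord <- ord$gene_id[order(ord$nb)]
  df <- tibble::as_tibble(object)
  df$gene_id <- factor(df$gene_id, levels = ord)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_index, y = .data$gene_id,
                                        fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "gray80") +
    ggplot2::labs(x = "bin from TSS", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if ("end_bin" %in% names(df)) {
    ends <- unique(df[, c("gene_id", "end_bin")])
    p <- p + ggplot2::geom_point(data = ends,
      ggplot2::aes(x = .data$end_bin, y = .data$gene_id), inherit.aes = FALSE,
      shape = "|", size = 1)
  }
  p
}

#' @rdname autoplot.velocity_matrix
#' @export
autoplot.aligned_matrix <- autoplot.velocity_matrix

#' MA plot of per-gene expression change
#'
#' @param ma Tibble from [ma_table()].
#' @param fc_highlight Absolute log2 fold-change threshold for highlighting.
#' @return A ggplot.
#' @export
plot_ma <- function(ma, fc_highlight = 1) {
  ma$highlight <- abs(ma$log2_fc) >= fc_highlight
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$base_mean, y = .data$log2_fc,
                                   color = .data$highlight)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "gray50",
                                           `TRUE` = "seagreen"),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change") +
    ggplot2::theme_minimal()
}
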