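#' Volcano plot of SNORD differential expression
#'
#' log2 fold change against -log10 raw p, with guide lines at the fold-change
#' and significance cutoffs, in the style used for SNORD screens.
#'
#' @param de Output of [diff_expression()].
#' @param alpha Raw-p guide line (default 0.05).
#' @param lfc_threshold Fold-change guide lines (default 1).
#' @return A ggplot object.
#' @export
plot_snord_volcano <- function(de, alpha = 0.05, lfc_threshold = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_snord_volcano() requires the ggplot2 package")
  d <- de[!de$filtered, ]
  ggplot2::ggplot(d, ggplot2::aes(x = log2fc, y = -log10(p),
                                  colour = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of Z-scored methylation scores
#'
#' Rows (sites) are clustered with Euclidean distance; columns (samples) are
#' kept in input order.
#'
#' @param m Numeric site x sample score matrix without missing values.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_methylation_heatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_methylation_heatmap() requires the pheatmap package")
  z <- zscore_rows(m)
  invisible(pheatmap::pheatmap(z, cluster_rows = TRUE, cluster_cols = FALSE,
                               clustering_distance_rows = "euclidean", ...))
}
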