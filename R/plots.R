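# Diagnostic plots. These are working views of a screen, not publication
# figures.

#' Manhattan-style plot of a screen
#'
#' -log10 p-values of one trait's screen by lifestyle category, with the
#' tentative-signal calls highlighted.
#'
#' @param signals An `exposcan_signals` table.
#' @param trait Trait to display.
#' @param mode Analysis mode (`"average"` or `"change"`).
#' @return A ggplot object.
#' @export
plot_screen_manhattan <- function(signals, trait, mode = "average") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_screen_manhattan requires the 'ggplot2' package",
         call. = FALSE)
  d <- as.data.frame(signals)
  d <- d[d$trait == trait & d$mode == mode & !is.na(d$p), , drop = FALSE]
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$neglog10p)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$tentative),
                         width = 0.25, height = 0, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = sprintf("%s (%s associations)", trait, mode),
                  colour = "tentative") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Correlation heatmap of exposures
#'
#' Heatmap of a correlation matrix with average-linkage ordering; masked
#' (incomputable) pairs are shown blank.
#'
#' @param corr Matrix from [correlation_matrix()].
#' @param filename Optional file to save to (passed to pheatmap).
#' @return The pheatmap object, invisibly.
#' @export
plot_correlation_heatmap <- function(corr, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_correlation_heatmap requires the 'pheatmap' package",
         call. = FALSE)
  d <- 1 - corr
  off <- d[upper.tri(d)]
  d[is.na(d)] <- mean(off, na.rm = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  invisible(pheatmap::pheatmap(corr, cluster_rows = hc, cluster_cols = hc,
                               na_col = "white", filename = filename))
}
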