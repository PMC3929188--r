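#' Plot methods
#'
#' `autoplot()` methods give the standard view of each result type:
#' expression profiles as a log2 RPKM histogram, fold-change tables as a
#' log2 fold-change histogram (log-scaled counts, so the regulated tails
#' stay visible), enrichment results as a ranked -log10 p dot plot.
#'
#' @param object A result object.
#' @param bin_width Histogram bin width on the log2 axis.
#' @param top_n Number of top-ranked categories to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @name thermoseq-plots
NULL

#' @rdname thermoseq-plots
#' @export
autoplot.thermo_expression <- function(object, bin_width = 0.5, ...) {
  dat <- filter(as_tibble(object), .data$rpkm > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$rpkm))) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "grey35", colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "log2(RPKM)", y = "Frequency",
                  title = paste0("Expression distribution, ", object$sample[1])) +
    ggplot2::theme_minimal()
}

#' @rdname thermoseq-plots
#' @export
autoplot.thermo_foldchange <- function(object, bin_width = 0.25, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$log2fc)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "grey35", colour = "white", linewidth = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "log2(fold change) 30C/25C", y = "log(Frequency)",
                  title = "Pseudocount-adjusted fold changes") +
    ggplot2::theme_minimal()
}

#' @rdname thermoseq-plots
#' @export
autoplot.thermo_enrichment <- function(object, top_n = 12, ...) {
  dat <- head(as_tibble(object), top_n)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$p_value), y = .data$label,
                                    size = .data$ratio)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10(P value)", y = NULL, size = "k/n",
                  title = sprintf("Category over-representation (R = %d, N = %d)",
                                  attr(object, "R"), attr(object, "N"))) +
    ggplot2::theme_minimal()
}

#' Two-sample expression scatter with highlighted families
#'
#' The classic two-condition comparison: per-gene log2 RPKM at 25 degrees
#' against 30 degrees for genes detected in both samples, grey background
#' points, coloured points for highlighted categories, and dashed
#' diagonals marking the two-fold band.
#'
#' @param table A `thermo_foldchange` tibble.
#' @param categories Optional membership tibble used to label genes (see
#'   [scatter_data()]).
#' @param fold Fold band drawn with dashed diagonals, default 2.
#' @return A ggplot object.
#' @export
plot_expression_scatter <- function(table, categories = NULL, fold = 2) {
  dat <- scatter_data(table, categories)
  bg <- filter(dat, .data$family == "other")
  fg <- filter(dat, .data$family != "other")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_rpkm_25,
                                         y = .data$log2_rpkm_30)) +
    ggplot2::geom_point(data = bg, colour = "grey70", size = 0.6) +
    ggplot2::geom_abline(intercept = c(-log2(fold), log2(fold)), slope = 1,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2(RPKM) 25C", y = "log2(RPKM) 30C") +
    ggplot2::theme_minimal()
  if (nrow(fg) > 0) {
    p <- p + ggplot2::geom_point(
      data = fg, ggplot2::aes(colour = .data$family), size = 1.4) +
      ggplot2::labs(colour = "Family")
  }
  p
}
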