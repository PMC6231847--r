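# Rendering of XmR charts: two stacked panels (X over time, moving range),
# centre lines, control limits, beyond-limit points highlighted, and an
# optional vertical event-annotation line. Rendering is cosmetic; all
# analysis and acceptance is on the numeric chart table.

#' Plot an XmR chart
#'
#' Draws the individuals (X) panel over the moving-range (mR) panel with
#' centre lines (solid), control limits (dashed), signals in red, and the
#' event annotation (if any) as a labelled vertical line.
#'
#' @param chart An `xmr_chart` from [build_xmr()].
#' @param title Optional plot title.
#' @return A patchwork/ggplot object (printable, savable with
#'   [ggplot2::ggsave()]).
#' @export
plot_xmr <- function(chart, title = NULL) {
  stopifnot(inherits(chart, "xmr_chart"))
  tab <- xmr_table(chart)
  tab$label <- factor(tab$label, levels = tab$label)

  base_theme <- ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))

  p_x <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$x,
                                           group = 1)) +
    ggplot2::geom_hline(yintercept = chart$x_bar, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(chart$x_lcl, chart$x_ucl),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$x_signal), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "X", title = title) +
    base_theme

  p_mr <- ggplot2::ggplot(tab[-1, ], ggplot2::aes(x = .data$label,
                                                  y = .data$mr, group = 1)) +
    ggplot2::geom_hline(yintercept = chart$mr_bar, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = chart$mr_ucl, linetype = "dashed",
                        linewidth = 0.4) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mr_signal), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "mR") +
    base_theme

  if (!is.null(chart$annotation)) {
    xpos <- chart$annotation$period
    p_x <- p_x +
      ggplot2::geom_vline(xintercept = xpos, linewidth = 0.7) +
      ggplot2::annotate("text", x = xpos, y = max(tab$x, chart$x_ucl),
                        label = chart$annotation$label, hjust = -0.1,
                        vjust = 1, size = 3)
    p_mr <- p_mr + ggplot2::geom_vline(xintercept = xpos - 1, linewidth = 0.7)
  }

  patchwork::wrap_plots(p_x, p_mr, ncol = 1, heights = c(2, 1))
}

#' @export
plot.xmr_chart <- function(x, ...) {
  print(plot_xmr(x, ...))
  invisible(x)
}
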