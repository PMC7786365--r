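#' Cost-effectiveness plane scatter plot
#'
#' @param samples A `psa_result` from [run_psa()].
#' @param wtp Optional willingness-to-pay threshold drawn as a line
#'   through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples, wtp = NULL) {
  p <- ggplot2::ggplot(as.data.frame(samples),
                       ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.5, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(intercept = 0, slope = wtp,
                                  linetype = "dashed", colour = "grey40")
  p
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve Data frame from [ceac()] (`wtp`, `probability`).
#' @param wtp_lines Optional thresholds marked with vertical lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, wtp_lines = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp_lines))
    p <- p + ggplot2::geom_vline(xintercept = wtp_lines, linetype = "dashed",
                                 colour = "grey40")
  p
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param tornado An `owsa_result` from [owsa()].
#' @param top Show only the `top` widest bars (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  df <- utils::head(as.data.frame(tornado), top)
  base <- attr(tornado, "base_icer")
  df$name <- factor(df$name, levels = rev(df$name))
  df$lo <- pmin(df$icer_at_low, df$icer_at_high)
  df$hi <- pmax(df$icer_at_low, df$icer_at_high)
  ggplot2::ggplot(df, ggplot2::aes(y = name)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
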