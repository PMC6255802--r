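#' Joint ZFst-ZHp scatter of a sweep scan
#'
#' The classic two-statistic outlier view: each point is a window, the
#' dashed lines are the empirical quantile thresholds, and flagged windows
#' (jointly extreme: high ZFst, low focal-population ZHp) are highlighted.
#'
#' @param rows A `sweep_scan` tibble, ideally after [call_outliers()].
#' @return A ggplot object.
#' @export
plot_scan <- function(rows) {
  has_outl <- "outlier" %in% names(rows)
  p <- ggplot2::ggplot(rows,
                       ggplot2::aes(x = .data$zhp_focal, y = .data$zfst)) +
    ggplot2::geom_point(
      if (has_outl) ggplot2::aes(colour = .data$outlier) else NULL,
      alpha = 0.6, size = 1) +
    ggplot2::labs(x = expression("ZH"[P] * " (focal population)"),
                  y = expression("ZF"[ST]),
                  colour = "outlier") +
    ggplot2::theme_minimal()
  if (!is.null(attr(rows, "zfst_threshold"))) {
    p <- p +
      ggplot2::geom_hline(yintercept = attr(rows, "zfst_threshold"),
                          linetype = "dashed") +
      ggplot2::geom_vline(xintercept = attr(rows, "zhp_threshold"),
                          linetype = "dashed")
  }
  if (has_outl) {
    p <- p + ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red"))
  }
  p
}

#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, ...) plot_scan(object)

#' LD decay curves
#'
#' Mean pairwise r-squared against physical distance, one curve per
#' population.
#'
#' @param curve Tibble from [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(curve) {
  ggplot2::ggplot(
    filter(curve, !is.na(.data$mean_r2)),
    ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                 y = .data$mean_r2, colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2),
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' @method autoplot locus_pca
#' @export
autoplot.locus_pca <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", 100 * object$varexp[1]),
      y = sprintf("PC2 (%.2f%%)", 100 * object$varexp[2])) +
    ggplot2::theme_minimal()
}
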