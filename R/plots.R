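#' Calibration plot by decile of predicted risk
#'
#' Observed event proportion against mean predicted risk in each decile,
#' with the identity line of perfect calibration.
#'
#' @param x A `crc_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_calibration <- function(x, ...) {
  stopifnot(inherits(x, "crc_calibration"))
  ggplot2::ggplot(x$deciles,
                  ggplot2::aes(x = .data$mean_predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Mean predicted risk (decile)",
                  y = "Observed event proportion",
                  title = "Calibration by decile of predicted risk") +
    ggplot2::theme_minimal()
}

#' @rdname plot_calibration
#' @param object A `crc_calibration` object.
#' @export
autoplot.crc_calibration <- function(object, ...) plot_calibration(object, ...)

#' Plot Nelson-Aalen cumulative hazard curves
#'
#' Step curves of cumulative hazard against age, one per group (e.g.
#' quintile of predicted 10-year risk).
#'
#' @param object A `crc_cumhaz` tibble from [nelson_aalen_by_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crc_cumhaz <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$cumhaz,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)", y = "Cumulative hazard",
                  colour = "Group",
                  title = "Nelson-Aalen cumulative hazard by group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
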