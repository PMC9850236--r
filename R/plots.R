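# ggplot2 displays for the result containers.

#' @describeIn cumulative_curve Plot the cumulative exposure-response curve
#'   with its 95% confidence ribbon.
#' @method autoplot er_curve
#' @param object An `er_curve`.
#' @param ... Unused.
#' @export
autoplot.er_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temp, y = .data$or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "ref_temp"),
                        linetype = "dotted") +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = sprintf("Cumulative OR (lag 0–%d)",
                  attr(object, "cb_spec")$lag_range[2]),
      title = if (!is.null(attr(object, "pm_level"))) {
        sprintf("Temperature–mortality curve at %.1f µg/m³",
                attr(object, "pm_level"))
      } else {
        "Temperature–mortality curve"
      }
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn lag_response Plot the lag-response pattern at the fitted
#'   temperature contrast.
#' @method autoplot lag_curve
#' @param object A `lag_curve`.
#' @param ... Unused.
#' @export
autoplot.lag_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "Lag (days)", y = "OR per lag",
      title = sprintf("Lag-response at %.1f vs %.1f °C",
                      attr(object, "x1"), attr(object, "x0"))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn modification_summary Plot the extreme-cold OR at each
#'   pollutant centering level.
#' @method autoplot modification_summary
#' @param object A `modification_summary`.
#' @export
autoplot.modification_summary <- function(object, ...) {
  df <- dplyr::mutate(object$levels,
                      level = factor(.data$level,
                                     levels = unique(.data$level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$or)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s level", toupper(object$pollutant)),
      y = "Extreme-cold cumulative OR",
      title = "Extreme-cold effect by pollution level"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn run_analysis Plot the report's overall curve with the MMT
#'   and extreme-cold temperature marked.
#' @method autoplot cold_report
#' @param object A `cold_report`.
#' @export
autoplot.cold_report <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::geom_vline(xintercept = object$extreme_cold$temp,
                        linetype = "dotdash", colour = "grey40") +
    ggplot2::annotate("text", x = object$mmt, y = Inf, label = "MMT",
                      vjust = 1.5, size = 3)
}
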