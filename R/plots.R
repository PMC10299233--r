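#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_rect
#'   geom_vline labs theme_minimal annotate
NULL

#' Plot a pore distribution
#'
#' @param object A `"pore_distribution"` from [pore_distribution()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pore_distribution <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$bin_mid, y = .data$density)) +
    geom_col(width = object$bins$bin_right - object$bins$bin_left,
             fill = "grey35", colour = "white", linewidth = 0.2) +
    labs(
      x = object$variable, y = "density",
      title = sprintf("Pore %s distribution (n = %d, %s bins)",
                      object$variable, object$summary$n, object$binning)
    ) +
    theme_minimal()
}

#' Plot a coherency-weighted orientation histogram
#'
#' @param object An `"orientation_histogram"` from
#'   [coherency_weighted_histogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  peak <- attr(object, "peak_angle_deg")
  ggplot(as_tibble(object), aes(x = .data$bin_mid, y = .data$density)) +
    geom_line(colour = "grey20") +
    geom_vline(xintercept = peak, linetype = 2, colour = "firebrick") +
    labs(
      x = "orientation (degrees)", y = "probability density (per degree)",
      title = sprintf("Peak at %.1f deg (90 = vertical channels)", peak)
    ) +
    theme_minimal()
}

#' Plot a fitted stress--strain curve with region annotations
#'
#' @param object A `"mech_fit"` from [fit_mechanics()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mech_fit <- function(object, ...) {
  s <- object$summary
  ggplot(object$curve, aes(x = .data$strain_pct, y = .data$stress_kPa)) +
    annotate("rect", xmin = s$toe_end_pct, xmax = s$linear_end_pct,
             ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    geom_line(colour = "grey20") +
    geom_vline(xintercept = c(s$toe_end_pct, s$linear_end_pct,
                              s$yield_end_pct),
               linetype = 3, colour = "grey50") +
    labs(
      x = "strain (%)", y = "stress (kPa)",
      title = sprintf("modulus %.0f kPa, UTS %.1f kPa, break at %.2f%%",
                      s$modulus_kPa, s$uts_kPa, s$elongation_break_pct)
    ) +
    theme_minimal()
}

#' Plot a temperature log against its nominal ramp profile
#'
#' @param log Tibble with `time_s`, `temp_C`.
#' @param nominal A [ramp_spec()].
#' @return A ggplot.
#' @export
plot_temperature_log <- function(log, nominal = ramp_spec()) {
  expected <- tibble(
    time_s = log$time_s,
    temp_C = pmax(nominal$start_temp_C +
                    nominal$ramp_rate_C_per_min / 60 * log$time_s,
                  nominal$hold_temp_C)
  )
  ggplot(log, aes(x = .data$time_s / 60, y = .data$temp_C)) +
    geom_line(colour = "grey20") +
    geom_line(data = expected, colour = "firebrick", linetype = 2) +
    labs(x = "time (min)", y = "temperature (deg C)",
         title = "Logged vs nominal freezing profile") +
    theme_minimal()
}
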