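#' Specification for a freeze-casting temperature ramp
#'
#' Nominal controlled-freezing profile of the thermoelectric freeze-casting
#' rig: a linear ramp at `ramp_rate_C_per_min` from `start_temp_C` down to
#' `hold_temp_C`, then a constant hold for `hold_min` minutes, logged at
#' `log_rate_hz`. Defaults reproduce the reference protocol: -1 degC/min to
#' -40 degC held for 90 min, logged at 10 Hz.
#'
#' @param start_temp_C Starting temperature, degrees Celsius.
#' @param ramp_rate_C_per_min Ramp rate (negative), degrees per minute.
#' @param hold_temp_C Hold plateau temperature (< start), degrees Celsius.
#' @param hold_min Hold duration, minutes.
#' @param log_rate_hz Logging rate, samples per second.
#' @param control_noise_sd_C Control jitter (Gaussian), degrees Celsius.
#' @param seed Integer seed.
#' @return A list of class `"ramp_spec"` with derived element `ramp_end_s`.
#' @seealso [gen_temperature_log()], [verify_ramp()]
#' @export
ramp_spec <- function(start_temp_C = 20,
                      ramp_rate_C_per_min = -1,
                      hold_temp_C = -40,
                      hold_min = 90,
                      log_rate_hz = 10,
                      control_noise_sd_C = 0,
                      seed = 1L) {
  stopifnot(
    ramp_rate_C_per_min < 0, hold_temp_C < start_temp_C,
    hold_min >= 0, log_rate_hz > 0, control_noise_sd_C >= 0
  )
  ramp_end_s <- (start_temp_C - hold_temp_C) / (-ramp_rate_C_per_min) * 60
  structure(
    list(
      start_temp_C = start_temp_C, ramp_rate_C_per_min = ramp_rate_C_per_min,
      hold_temp_C = hold_temp_C, hold_min = hold_min,
      log_rate_hz = log_rate_hz, control_noise_sd_C = control_noise_sd_C,
      seed = as.integer(seed), ramp_end_s = ramp_end_s
    ),
    class = "ramp_spec"
  )
}

#' Generate a synthetic freeze-casting temperature log
#'
#' Samples the nominal ramp-and-hold profile of a [ramp_spec()] at
#' `log_rate_hz`, with optional Gaussian control jitter. The sample at the
#' ramp/hold change point belongs to the ramp segment; with the default
#' 90 min hold at 10 Hz the hold segment holds exactly 54,000 samples.
#'
#' @param spec A [ramp_spec()].
#' @return Tibble with columns `time_s`, `temp_C` and attribute `spec`.
#' @export
gen_temperature_log <- function(spec) {
  stopifnot(inherits(spec, "ramp_spec"))
  total_s <- spec$ramp_end_s + spec$hold_min * 60
  n <- round(total_s * spec$log_rate_hz)
  t <- (0:n) / spec$log_rate_hz
  temp <- pmax(spec$start_temp_C + spec$ramp_rate_C_per_min / 60 * t,
               spec$hold_temp_C)
  if (spec$control_noise_sd_C > 0) {
    temp <- with_seed(spec$seed,
                      temp + rnorm(length(temp), 0, spec$control_noise_sd_C))
  }
  out <- tibble(time_s = t, temp_C = temp)
  attr(out, "spec") <- spec
  out
}
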