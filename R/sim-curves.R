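#' Specification for a synthetic J-shaped stress--strain curve
#'
#' Parameterizes the tensile response typical of hydrated freeze-cast
#' biopolymer scaffolds: a compliant toe region where fibres uncrimp, a linear
#' elastic region whose slope is the viscoelastic modulus, a yield region
#' where the slope decays to zero at the stress peak (defibrillation), and an
#' optional short post-peak decline to the end of the test. Defaults use the
#' crosslinked 60/40 collagen/chitosan blend magnitudes (modulus 2499.5 kPa,
#' maximum tensile strength 91.8 kPa) with region extents inside the typical
#' ~0--3 / ~3--6 / ~6--7 % layout.
#'
#' The toe is a quadratic ramp in slope (stress rises as strain cubed) so the
#' slope is continuous and equals `modulus_kPa` at `toe_end_pct`; the yield
#' segment is a monotone cubic Hermite from (`linear_end_pct`, slope =
#' modulus) to (`yield_end_pct`, stress = `uts_kPa`, slope = 0). Specs whose
#' `uts_kPa` cannot be reached monotonically from the end of the linear region
#' (or would be overshot before it) are rejected.
#'
#' @param modulus_kPa Slope of the linear region, kPa per unit strain
#'   (strain as a fraction).
#' @param uts_kPa Maximum tensile strength (peak stress), kPa.
#' @param break_strain_pct Elongation at break, percent strain; the curve
#'   terminates there.
#' @param toe_end_pct,linear_end_pct,yield_end_pct Region boundaries, percent
#'   strain; the stress peak sits at `yield_end_pct`.
#' @param post_peak_drop_frac Fractional stress decline between the peak and
#'   the break point (0 gives a plateau). Kept below typical failure-detection
#'   thresholds so the test ends "at end of course".
#' @param sample_rate_hz Acquisition rate, samples per second.
#' @param strain_rate_pct_per_s Loading rate, percent strain per second.
#' @param noise_sd_kPa Additive Gaussian stress noise, kPa.
#' @param seed Integer seed.
#' @return A list of class `"curve_spec"` with derived element
#'   `linear_start_stress_kPa` (stress at the toe/linear boundary).
#' @seealso [gen_stress_strain()]
#' @export
curve_spec <- function(modulus_kPa = 2499.5,
                       uts_kPa = 91.8,
                       break_strain_pct = 7.5,
                       toe_end_pct = 3,
                       linear_end_pct = 5,
                       yield_end_pct = 6.5,
                       post_peak_drop_frac = 0.1,
                       sample_rate_hz = 100,
                       strain_rate_pct_per_s = 1,
                       noise_sd_kPa = 0,
                       seed = 1L) {
  stopifnot(
    modulus_kPa > 0, uts_kPa > 0,
    toe_end_pct > 0, toe_end_pct < linear_end_pct,
    linear_end_pct < yield_end_pct, yield_end_pct <= break_strain_pct,
    post_peak_drop_frac >= 0, post_peak_drop_frac < 1,
    sample_rate_hz > 0, strain_rate_pct_per_s > 0, noise_sd_kPa >= 0
  )
  e_pct <- modulus_kPa / 100           # kPa per percent strain
  sigma2 <- e_pct * toe_end_pct / 3 + e_pct * (linear_end_pct - toe_end_pct)
  rise <- uts_kPa - sigma2
  gap <- yield_end_pct - linear_end_pct
  if (rise <= 0) {
    abort(sprintf(
      paste0("uts_kPa (%.1f) is unreachable: stress already reaches %.1f kPa ",
             "at the end of the linear region given modulus and boundaries"),
      uts_kPa, sigma2
    ))
  }
  # the cubic yield segment has a monotonically decreasing slope (E at the
  # linear end, 0 at the peak) iff its secant lies in [E/3, 2E/3]
  if (e_pct * gap > 3 * rise * (1 + 1e-9)) {
    abort(sprintf(
      paste0("uts_kPa (%.1f) cannot be approached monotonically: the linear ",
             "slope over the yield span would overshoot it ",
             "(need uts - %.1f >= %.2f kPa)"),
      uts_kPa, sigma2, e_pct * gap / 3
    ))
  }
  if (rise > (2 / 3) * e_pct * gap * (1 + 1e-9)) {
    abort(sprintf(
      paste0("yield segment slope would have to rise above the modulus to ",
             "reach uts_kPa (%.1f): need uts - %.1f <= %.2f kPa (widen the ",
             "yield span or lower uts_kPa)"),
      uts_kPa, sigma2, (2 / 3) * e_pct * gap
    ))
  }
  if (yield_end_pct == break_strain_pct && post_peak_drop_frac > 0) {
    abort("post_peak_drop_frac must be 0 when the peak sits at the break point")
  }
  structure(
    list(
      modulus_kPa = modulus_kPa, uts_kPa = uts_kPa,
      break_strain_pct = break_strain_pct, toe_end_pct = toe_end_pct,
      linear_end_pct = linear_end_pct, yield_end_pct = yield_end_pct,
      post_peak_drop_frac = post_peak_drop_frac,
      sample_rate_hz = sample_rate_hz,
      strain_rate_pct_per_s = strain_rate_pct_per_s,
      noise_sd_kPa = noise_sd_kPa, seed = as.integer(seed),
      linear_start_stress_kPa = e_pct * toe_end_pct / 3,
      linear_end_stress_kPa = sigma2
    ),
    class = "curve_spec"
  )
}

# Cubic Hermite segment on [x0, x1] with values y0, y1 and slopes m0, m1.
hermite_seg <- function(x, x0, x1, y0, y1, m0, m1) {
  L <- x1 - x0
  s <- (x - x0) / L
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * y0 + h10 * L * m0 + h01 * y1 + h11 * L * m1
}

#' Generate a synthetic stress--strain curve
#'
#' Samples the piecewise curve described by a [curve_spec()] at
#' `strain_rate / sample_rate` percent-strain increments from zero to the
#' break strain. The true region boundaries and parameters are attached as
#' attributes (`regions`, `spec`) for ground-truth comparisons.
#'
#' @param spec A [curve_spec()].
#' @return A tibble with columns `time_s`, `strain_pct`, `stress_kPa` and
#'   attributes `spec` and `regions`.
#' @examples
#' cv <- gen_stress_strain(curve_spec(noise_sd_kPa = 0))
#' max(cv$stress_kPa)   # equals uts_kPa
#' @export
gen_stress_strain <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  step <- spec$strain_rate_pct_per_s / spec$sample_rate_hz
  n <- round(spec$break_strain_pct / step)
  strain <- (0:n) * step
  e_pct <- spec$modulus_kPa / 100
  t1 <- spec$toe_end_pct; t2 <- spec$linear_end_pct
  t3 <- spec$yield_end_pct; tb <- spec$break_strain_pct
  s1 <- spec$linear_start_stress_kPa
  s2 <- spec$linear_end_stress_kPa
  uts <- spec$uts_kPa
  stress <- numeric(length(strain))
  toe <- strain <= t1
  stress[toe] <- e_pct * strain[toe]^3 / (3 * t1^2)
  lin <- strain > t1 & strain <= t2
  stress[lin] <- s1 + e_pct * (strain[lin] - t1)
  yld <- strain > t2 & strain <= t3
  stress[yld] <- hermite_seg(strain[yld], t2, t3, s2, uts, e_pct, 0)
  post <- strain > t3
  if (any(post)) {
    y_end <- uts * (1 - spec$post_peak_drop_frac)
    m_end <- -(uts - y_end) / (tb - t3)   # secant end slope: monotone decline
    stress[post] <- hermite_seg(strain[post], t3, tb, uts, y_end, 0, m_end)
  }
  if (spec$noise_sd_kPa > 0) {
    stress <- with_seed(spec$seed,
                        stress + rnorm(length(stress), 0, spec$noise_sd_kPa))
  }
  out <- tibble(
    time_s = strain / spec$strain_rate_pct_per_s,
    strain_pct = strain,
    stress_kPa = stress
  )
  attr(out, "spec") <- spec
  attr(out, "regions") <- tibble(
    toe_end_pct = t1, linear_end_pct = t2, yield_end_pct = t3,
    break_strain_pct = tb, modulus_kPa = spec$modulus_kPa, uts_kPa = uts
  )
  out
}

#' Fabricate a traction log from a stress--strain curve
#'
#' Inverse of [to_stress_strain()]: builds the raw (time, displacement, force)
#' log a traction rig would record for a given curve and specimen geometry,
#' including the pre-tension phase (force ramp at `pretension_rate_g_per_s`
#' with the specimen still unloaded). Round-tripping through
#' [to_stress_strain()] recovers the curve to numerical precision.
#'
#' @param curve Tibble with `strain_pct` and `stress_kPa` (and `time_s`).
#' @param gauge_length_mm,diameter_mm Specimen geometry.
#' @param pretension_g Pre-tension, grams-force.
#' @param pretension_rate_g_per_s Pre-tension loading rate, grams per second.
#' @return A tibble with columns `time_s`, `displacement_mm`, `force_N` and
#'   attributes `gauge_length_mm`, `diameter_mm`.
#' @export
curve_to_traction_log <- function(curve, gauge_length_mm = 35, diameter_mm = 5,
                                  pretension_g = 3,
                                  pretension_rate_g_per_s = 1) {
  stopifnot(all(c("time_s", "strain_pct", "stress_kPa") %in% names(curve)),
            gauge_length_mm > 0, diameter_mm > 0, pretension_g > 0)
  g <- 9.80665
  f_pre <- pretension_g / 1000 * g
  area_m2 <- pi * (diameter_mm / 2000)^2
  dt <- median(diff(curve$time_s))
  pre_t <- seq(0, pretension_g / pretension_rate_g_per_s - dt, by = dt)
  pre <- tibble(
    time_s = pre_t,
    displacement_mm = 0,
    force_N = pre_t * pretension_rate_g_per_s / 1000 * g
  )
  pull <- tibble(
    time_s = max(pre_t) + dt + curve$time_s,
    displacement_mm = curve$strain_pct / 100 * gauge_length_mm,
    force_N = f_pre + curve$stress_kPa * 1000 * area_m2
  )
  out <- dplyr::bind_rows(pre, pull)
  attr(out, "gauge_length_mm") <- gauge_length_mm
  attr(out, "diameter_mm") <- diameter_mm
  out
}

#' Sample feasible random curve specifications
#'
#' Draws tensile parameters for recovery studies: modulus uniform on
#' `modulus_range`, maximum tensile strength uniform on `uts_range`, and noise
#' uniform on `noise_frac_range` times the strength. Region boundaries are
#' derived from the drawn parameters so every spec is feasible: the linear
#' region ends where stress reaches two thirds of the strength, the toe
#' occupies the first half of that span, and the yield span is half its
#' monotonicity limit.
#'
#' @param n Number of specs.
#' @param modulus_range,uts_range,noise_frac_range Sampling ranges.
#' @param sample_rate_hz,strain_rate_pct_per_s Acquisition parameters.
#' @param seed Integer seed.
#' @return A list of [curve_spec()] objects.
#' @export
sample_curve_specs <- function(n,
                               modulus_range = c(500, 4000),
                               uts_range = c(50, 150),
                               noise_frac_range = c(0, 0.05),
                               sample_rate_hz = 100,
                               strain_rate_pct_per_s = 1,
                               seed = 1L) {
  with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      e <- runif(1, modulus_range[1], modulus_range[2])
      uts <- runif(1, uts_range[1], uts_range[2])
      nf <- runif(1, noise_frac_range[1], noise_frac_range[2])
      e_pct <- e / 100
      t2 <- uts / e_pct                    # sigma2 = (2/3) uts with t1 = t2/2
      t1 <- t2 / 2
      gap <- 0.5 * (3 * (uts / 3) / e_pct)  # half the monotonicity limit
      t3 <- t2 + gap
      tb <- t3 + 0.25 * gap
      curve_spec(
        modulus_kPa = e, uts_kPa = uts,
        break_strain_pct = tb, toe_end_pct = t1, linear_end_pct = t2,
        yield_end_pct = t3, post_peak_drop_frac = 0.1,
        sample_rate_hz = sample_rate_hz,
        strain_rate_pct_per_s = strain_rate_pct_per_s,
        noise_sd_kPa = nf * uts,
        seed = sample.int(.Machine$integer.max, 1)
      )
    })
  })
}
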