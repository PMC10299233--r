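test_that("engineering stress conversion matches the closed form", {
  expect_equal(engineering_stress_kpa(1, 5), 1 / (pi * 0.0025^2) / 1000,
               tolerance = 1e-12)
  expect_equal(engineering_stress_kpa(1, 5), 50.92958, tolerance = 1e-6)
  # doubling the diameter quarters the stress
  expect_equal(engineering_stress_kpa(1, 10), engineering_stress_kpa(1, 5) / 4)
})

test_that("displacement converts to percent strain on the gauge length", {
  log <- tibble::tibble(
    time_s = 0:100 / 10,
    displacement_mm = seq(0, 0.35, length.out = 101),
    force_N = seq(0.03, 2, length.out = 101)
  )
  cv <- to_stress_strain(log, gauge_length_mm = 35, diameter_mm = 5)
  expect_equal(max(cv$strain_pct), 1, tolerance = 1e-9)
})

test_that("fabricated logs round-trip to the source curve", {
  cv <- gen_stress_strain(curve_spec())
  log <- curve_to_traction_log(cv, gauge_length_mm = 35, diameter_mm = 5)
  back <- to_stress_strain(log, gauge_length_mm = 35, diameter_mm = 5)
  expect_equal(back$strain_pct, cv$strain_pct, tolerance = 1e-12)
  expect_equal(back$stress_kPa, cv$stress_kPa, tolerance = 1e-12)
})

test_that("tests that never reach pre-tension are rejected", {
  log <- tibble::tibble(time_s = 1:10, displacement_mm = 1:10 / 10,
                        force_N = rep(0.001, 10))
  expect_error(to_stress_strain(log, 35, 5), "never reaches")
})

test_that("region boundaries are recovered on noise-free curves", {
  sp <- typical_curve_spec()
  cv <- gen_stress_strain(sp)
  r <- segment_regions(cv)
  expect_false(r$fallback)
  expect_lt(abs(r$toe_end_pct - sp$toe_end_pct), 0.3)
  expect_lt(abs(r$linear_end_pct - sp$linear_end_pct), 0.3)
  expect_equal(r$yield_end_pct, sp$yield_end_pct, tolerance = 0.1)
  expect_true(r$end_of_course)  # 10% post-peak decline never trips 30%
  expect_equal(r$failure_strain_pct, sp$break_strain_pct)
})

test_that("a pure linear curve has an empty toe and spans the data", {
  cv <- tibble::tibble(strain_pct = (0:500) / 50,
                       stress_kPa = 12 * (0:500) / 50)
  r <- segment_regions(cv)
  expect_equal(r$toe_end_pct, 0)
  expect_equal(r$linear_end_pct, 10)
  s <- extract_summary(cv, regions = r)
  expect_equal(s$modulus_kPa, 1200, tolerance = 1e-9)
  expect_equal(s$fit_r2, 1)
})

test_that("a sharp stress drop is detected as failure", {
  sp <- typical_curve_spec()
  cv <- gen_stress_strain(sp)
  dropped <- dplyr::bind_rows(
    cv,
    tibble::tibble(
      time_s = max(cv$time_s) + (1:30) / 100,
      strain_pct = max(cv$strain_pct) + (1:30) / 100,
      stress_kPa = 0.4 * cv$stress_kPa[nrow(cv)]
    )
  )
  r <- segment_regions(dropped)
  expect_false(r$end_of_course)
  expect_equal(r$failure_strain_pct, max(cv$strain_pct) + 0.01,
               tolerance = 0.02)
})

test_that("noise-free feature extraction is essentially exact", {
  sp <- curve_spec(modulus_kPa = 2500, uts_kPa = 91.8, noise_sd_kPa = 0)
  s <- extract_summary(gen_stress_strain(sp))
  expect_lt(abs(s$modulus_kPa - 2500) / 2500, 0.01)
  expect_identical(s$uts_kPa, 91.8)
  expect_equal(s$elongation_break_pct, sp$break_strain_pct)
})

test_that("features are recovered across moduli and noise levels", {
  specs <- sample_curve_specs(40, seed = 77)
  err <- purrr::map_dfr(specs, function(sp) {
    s <- suppressWarnings(extract_summary(gen_stress_strain(sp)))
    tibble::tibble(
      modulus = abs(s$modulus_kPa - sp$modulus_kPa) / sp$modulus_kPa,
      uts = abs(s$uts_kPa - sp$uts_kPa) / sp$uts_kPa,
      elong = abs(s$elongation_break_pct - sp$break_strain_pct)
    )
  })
  expect_lt(median(err$modulus), 0.05)
  expect_lt(median(err$uts), 0.02)
  expect_lt(median(err$elong), 0.01 + 0.1)
})

test_that("positive noise does not move the censored break point", {
  clean <- extract_summary(gen_stress_strain(typical_curve_spec()))
  noisy <- suppressWarnings(extract_summary(
    gen_stress_strain(typical_curve_spec(noise_sd_kPa = 2, seed = 5))
  ))
  expect_equal(noisy$elongation_break_pct, clean$elongation_break_pct)
})

test_that("modulus is invariant to consistent geometry rescaling", {
  cv <- gen_stress_strain(curve_spec())
  log <- curve_to_traction_log(cv, gauge_length_mm = 35, diameter_mm = 5)
  log2 <- log
  log2$displacement_mm <- log$displacement_mm * 2  # same specimen, 2x gauge
  s1 <- extract_summary(to_stress_strain(log, 35, 5))
  s2 <- extract_summary(to_stress_strain(log2, 70, 5))
  expect_equal(s2$modulus_kPa, s1$modulus_kPa, tolerance = 1e-9)
})

test_that("mech_fit objects expose broom-style methods", {
  fit <- fit_mechanics(gen_stress_strain(curve_spec()),
                       specimen = list(composition = "60/40",
                                       crosslinked = TRUE))
  td <- tidy(fit)
  expect_equal(td$feature, c("modulus", "uts", "elongation_break"))
  gl <- glance(fit)
  expect_equal(gl$composition, "60/40")
  expect_equal(nrow(gl), 1)
  expect_output(print(fit), "modulus")
})

test_that("curves shorter than 50 samples before failure are rejected", {
  cv <- tibble::tibble(strain_pct = (0:30) / 10, stress_kPa = (0:30) * 2)
  expect_error(segment_regions(cv), "50 samples")
})
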