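# Fixture builders shared across tests (everything is generated in code).

# A pore-field spec whose image area scales with the requested pore count so
# rejection-sampling placement stays feasible at the default pore sizes.
recovery_field_spec <- function(n_pores, seed) {
  # ~1100 occupied px per pore (mean area + clearance) at <= ~35% fill
  side <- max(384L, as.integer(ceiling(sqrt(n_pores * 3300))))
  pore_field_spec(
    image_size = c(side, side), pixel_scale = 2, n_pores = n_pores,
    noise_sd = 0, allow_overlap = FALSE, seed = seed
  )
}

# A modest feasible curve spec for segmentation tests with the typical
# ~0-3 / 3-6 % region layout.
typical_curve_spec <- function(noise_sd_kPa = 0, seed = 1L) {
  curve_spec(
    modulus_kPa = 1000, uts_kPa = 52, break_strain_pct = 10,
    toe_end_pct = 3, linear_end_pct = 6, yield_end_pct = 8,
    noise_sd_kPa = noise_sd_kPa, seed = seed
  )
}

expect_ggplot <- function(x) testthat::expect_s3_class(x, "ggplot")

# Shared end-to-end pipeline fixtures.
make_inputs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- gen_pore_field(pore_field_spec(n_pores = 15, image_size = c(320, 320),
                                       seed = 9))
  img_path <- file.path(dir, "transversal.png")
  write_gray_image(pf$image, img_path)
  ch_path <- file.path(dir, "longitudinal.png")
  write_gray_image(
    gen_channel_field(channel_field_spec(stripe_angle_deg = 90)), ch_path
  )
  cv <- gen_stress_strain(curve_spec())
  log_path <- file.path(dir, "traction.csv")
  readr::write_csv(curve_to_traction_log(cv), log_path)
  ramp <- gen_temperature_log(ramp_spec(hold_min = 2, ramp_rate_C_per_min = -20,
                                        log_rate_hz = 2))
  ramp_path <- file.path(dir, "ramp.csv")
  readr::write_csv(ramp, ramp_path)
  stats_path <- file.path(dir, "tidy.csv")
  set.seed(1)
  d <- expand.grid(composition = c("coll", "60_40"),
                   crosslinked = c("no", "yes"), rep = 1:6)
  d$modulus_kPa <- rnorm(nrow(d), 1000) + 1500 * (d$crosslinked == "yes")
  readr::write_csv(d, stats_path)
  list(img = img_path, channel = ch_path, log = log_path, ramp = ramp_path,
       stats = stats_path)
}

make_config <- function(paths, out_dir) {
  list(
    seed = 7,
    out_dir = out_dir,
    pores = list(images = paths$img, pixel_scale = 2),
    orientation = list(images = paths$channel, window_sigma = 2,
                       bin_width_deg = 1),
    mechanics = list(logs = paths$log, gauge_length_mm = 35, diameter_mm = 5),
    stats = list(data = paths$stats, response = "modulus_kPa",
                 factors = c("composition", "crosslinked"),
                 tukey_factor = "composition"),
    ramp = list(log = paths$ramp, ramp_rate_C_per_min = -20, hold_min = 2,
                log_rate_hz = 2, tolerance_C = 0.5)
  )
}

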