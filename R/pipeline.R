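#' Verify a freeze-casting temperature log against its nominal profile
#'
#' Checks a logged temperature trace against the nominal ramp-and-hold
#' protocol: least-squares ramp rate over the ramp segment, plateau mean and
#' standard deviation over the hold segment, and the maximum absolute
#' deviation from the nominal profile, with a pass/fail verdict at
#' `tolerance_C`. The ramp/hold split is taken from the nominal profile's
#' change point, never from the (possibly noisy) log itself.
#'
#' @param log Tibble with `time_s`, `temp_C` (strictly increasing time).
#' @param nominal A [ramp_spec()] describing the intended protocol.
#' @param tolerance_C Maximum tolerated absolute deviation, degrees Celsius.
#' @return One-row tibble: `fitted_rate_C_per_min`, `plateau_mean_C`,
#'   `plateau_sd_C`, `max_abs_dev_C`, `n_ramp`, `n_hold`, `pass`, `note`
#'   (diagnostic such as a plateau offset, or `NA`).
#' @examples
#' log <- gen_temperature_log(ramp_spec())
#' verify_ramp(log, ramp_spec(), tolerance_C = 0.5)
#' @export
verify_ramp <- function(log, nominal = ramp_spec(), tolerance_C = 1) {
  stopifnot(inherits(nominal, "ramp_spec"), tolerance_C > 0,
            all(c("time_s", "temp_C") %in% names(log)))
  if (nrow(log) < 2) abort("ramp log needs at least 2 samples")
  if (any(diff(log$time_s) <= 0)) abort("time_s must be strictly increasing")
  ramp <- log$time_s <= nominal$ramp_end_s
  hold <- !ramp
  expected <- pmax(
    nominal$start_temp_C + nominal$ramp_rate_C_per_min / 60 * log$time_s,
    nominal$hold_temp_C
  )
  dev <- abs(log$temp_C - expected)
  rate <- if (sum(ramp) >= 2) {
    unname(coef(lm(log$temp_C[ramp] ~ log$time_s[ramp]))[2]) * 60
  } else {
    NA_real_
  }
  pm <- if (any(hold)) mean(log$temp_C[hold]) else NA_real_
  ps <- if (sum(hold) > 1) sd(log$temp_C[hold]) else NA_real_
  maxdev <- max(dev)
  note <- NA_character_
  if (is.finite(pm) && abs(pm - nominal$hold_temp_C) > tolerance_C) {
    note <- sprintf("plateau offset: hold mean %.2f C vs nominal %.2f C",
                    pm, nominal$hold_temp_C)
  }
  tibble(
    fitted_rate_C_per_min = rate,
    plateau_mean_C = pm, plateau_sd_C = ps,
    max_abs_dev_C = maxdev,
    n_ramp = sum(ramp), n_hold = sum(hold),
    pass = maxdev <= tolerance_C,
    note = note
  )
}

stage_abort <- function(stage, msg) {
  abort(sprintf("[stage %s] %s", stage, msg), class = "pipeline_stage_error")
}

#' Run the configured analysis pipeline
#'
#' Orchestrates the configured stages -- pore analysis, orientation analysis,
#' mechanics, group statistics and ramp verification -- over lists of input
#' files, writing per-stage CSV outputs and a machine-readable JSON manifest
#' (parameter echo, package version, seed) into `config$out_dir`. All inputs
#' are checked before any stage runs, and outputs are deterministic given the
#' inputs and seed: the manifest deliberately records no wall-clock time, so
#' two runs of the same configuration are byte-identical.
#'
#' The configuration is a named list (or a YAML/JSON file path) with optional
#' entries `pores`, `orientation`, `mechanics`, `stats`, `ramp`, plus
#' `out_dir` and `seed`. Each stage entry carries its module's parameters:
#' \describe{
#'   \item{pores}{`images` (paths), `pixel_scale`, and optionally `method`,
#'     `polarity`, `connectivity`, `min_area_px`.}
#'   \item{orientation}{`images` (paths), optionally `roi`, `window_sigma`,
#'     `bin_width_deg`, `positions`.}
#'   \item{mechanics}{`logs` (paths), `gauge_length_mm`, `diameter_mm`,
#'     optionally `pretension_g`.}
#'   \item{stats}{`data` (CSV path or data frame), `response`, `factors`,
#'     optionally `max_order`, `ss_type`, `tukey_factor`.}
#'   \item{ramp}{`log` (CSV path or data frame), optionally the
#'     [ramp_spec()] fields and `tolerance_C`.}
#' }
#'
#' @param config Named list or path to a YAML/JSON configuration file.
#' @return A list of class `"pipeline_report"`: `stages` (tibble with one row
#'   per stage run), `outputs` (character vector of files written),
#'   `manifest` (path to the JSON manifest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(
      ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      abort("config file must be YAML or JSON")
    )
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # pre-flight: every referenced input must exist before any stage runs
  paths <- c(
    config$pores$images, config$orientation$images, config$mechanics$logs,
    if (is.character(config$stats$data)) config$stats$data,
    if (is.character(config$ramp$log)) config$ramp$log
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing input path(s): %s", paste(missing, collapse = ", ")))
  }

  outputs <- character()
  stages <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    outputs <<- c(outputs, p)
    p
  }

  with_seed(seed, {
    if (!is.null(config$pores)) {
      pc <- config$pores
      if (is.null(pc$pixel_scale)) stage_abort("pores", "pixel_scale is required")
      recs <- purrr::imap(pc$images, function(pth, i) {
        r <- analyze_pores(
          read_gray_image(pth, pixel_scale = pc$pixel_scale),
          method = pc$method %||% "otsu",
          polarity = pc$polarity %||% "dark_pores",
          connectivity = pc$connectivity %||% 8,
          min_area_px = pc$min_area_px %||% 5
        )
        dplyr::mutate(r, image = basename(pth), .before = 1)
      })
      all_recs <- dplyr::bind_rows(recs)
      emit(all_recs, "pores.csv")
      counts <- dplyr::count(all_recs, .data$image, name = "pore_count")
      emit(counts, "pore_counts.csv")
      stages$pores <- tibble(
        stage = "pores", n_inputs = length(pc$images),
        n_records = nrow(all_recs),
        detail = sprintf("%d pores over %d image(s)", nrow(all_recs),
                         length(pc$images))
      )
    }

    if (!is.null(config$orientation)) {
      oc <- config$orientation
      hists <- purrr::map(oc$images, function(pth) {
        analyze_orientation(
          read_gray_image(pth, pixel_scale = oc$pixel_scale %||% 1),
          roi = oc$roi,
          window_sigma = oc$window_sigma %||% 2,
          bin_width_deg = oc$bin_width_deg %||% 1
        )
      })
      hist_df <- purrr::imap(hists, function(h, i) {
        dplyr::mutate(as_tibble(h), image = basename(oc$images[[i]]),
                      .before = 1)
      }) |> dplyr::bind_rows()
      emit(hist_df, "orientation_histograms.csv")
      summ <- summarize_alignment(hists, positions = oc$positions)
      emit(summ, "orientation_summary.csv")
      stages$orientation <- tibble(
        stage = "orientation", n_inputs = length(oc$images),
        n_records = nrow(summ),
        detail = sprintf("mean peak %.1f deg", mean(summ$mean_peak_deg))
      )
    }

    if (!is.null(config$mechanics)) {
      mc <- config$mechanics
      if (is.null(mc$gauge_length_mm) || is.null(mc$diameter_mm)) {
        stage_abort("mechanics", "gauge_length_mm and diameter_mm are required")
      }
      summ <- purrr::map(mc$logs, function(pth) {
        cv <- to_stress_strain(
          read_traction_log(pth),
          gauge_length_mm = mc$gauge_length_mm,
          diameter_mm = mc$diameter_mm,
          pretension_g = mc$pretension_g %||% 3
        )
        dplyr::mutate(extract_summary(cv), log = basename(pth), .before = 1)
      }) |> dplyr::bind_rows()
      emit(summ, "mechanics_summary.csv")
      stages$mechanics <- tibble(
        stage = "mechanics", n_inputs = length(mc$logs), n_records = nrow(summ),
        detail = sprintf("mean modulus %.0f kPa", mean(summ$modulus_kPa))
      )
    }

    if (!is.null(config$stats)) {
      sc <- config$stats
      dat <- if (is.character(sc$data)) {
        readr::read_csv(sc$data, show_col_types = FALSE)
      } else {
        sc$data
      }
      fit <- anova_factorial(dat, sc$response, sc$factors,
                             max_order = sc$max_order %||% length(sc$factors),
                             ss_type = sc$ss_type %||% "II")
      emit(tidy(fit), "anova.csv")
      n_pairs <- 0L
      if (!is.null(sc$tukey_factor)) {
        tk <- tukey_kramer(dat, sc$response, sc$tukey_factor)
        emit(tk, "tukey.csv")
        n_pairs <- nrow(tk)
      }
      stages$stats <- tibble(
        stage = "stats", n_inputs = 1L, n_records = nrow(tidy(fit)),
        detail = sprintf("%d terms, %d pairwise comparisons",
                         nrow(tidy(fit)), n_pairs)
      )
    }

    if (!is.null(config$ramp)) {
      rc <- config$ramp
      log <- if (is.character(rc$log)) read_ramp_log(rc$log) else rc$log
      nominal <- ramp_spec(
        start_temp_C = rc$start_temp_C %||% 20,
        ramp_rate_C_per_min = rc$ramp_rate_C_per_min %||% -1,
        hold_temp_C = rc$hold_temp_C %||% -40,
        hold_min = rc$hold_min %||% 90,
        log_rate_hz = rc$log_rate_hz %||% 10
      )
      rep <- verify_ramp(log, nominal, tolerance_C = rc$tolerance_C %||% 1)
      emit(rep, "ramp_verification.csv")
      stages$ramp <- tibble(
        stage = "ramp", n_inputs = 1L, n_records = 1L,
        detail = sprintf("fitted rate %.3f C/min, %s", rep$fitted_rate_C_per_min,
                         if (rep$pass) "pass" else "FAIL")
      )
    }
  })

  manifest <- file.path(out_dir, "manifest.json")
  cfg_echo <- config
  cfg_echo$out_dir <- NULL   # implied by the manifest location; keeping it
                             # out makes runs to different directories compare
                             # byte-identical
  jsonlite::write_json(
    list(
      package = "scaffoldquant",
      version = as.character(utils::packageVersion("scaffoldquant")),
      seed = seed,
      config = cfg_echo,
      outputs = basename(outputs)
    ),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  structure(
    list(stages = dplyr::bind_rows(stages), outputs = outputs,
         manifest = manifest),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$stages)
  cat(sprintf("%d output file(s); manifest: %s\n", length(x$outputs),
              x$manifest))
  invisible(x)
}
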