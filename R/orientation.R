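#' Sobel image gradients over a region of interest
#'
#' Applies 3x3 Sobel filters to estimate the intensity gradient in the x
#' (column) and y (row) directions over a rectangular ROI. Borders are
#' handled by reflection. This is the first stage of the micro-channel
#' alignment analysis of longitudinal-cut images.
#'
#' @param img Numeric matrix.
#' @param roi Integer vector `c(x0, y0, x1, y1)` (column/row bounds,
#'   inclusive). Default: full image minus a 3-pixel border.
#' @return A list of class `"image_gradients"` with matrices `gx`, `gy` and
#'   the `roi` used.
#' @export
compute_gradients <- function(img, roi = NULL) {
  stopifnot(is.matrix(img), is.numeric(img))
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(roi)) {
    b <- if (nr > 8 && nc > 8) 3L else 0L
    roi <- c(1L + b, 1L + b, nc - b, nr - b)
  }
  stopifnot(length(roi) == 4L)
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x0 < 1 || y0 < 1 || x1 > nc || y1 > nr) {
    abort("roi outside image bounds")
  }
  if (x1 - x0 < 2 || y1 - y0 < 2) abort("roi must be at least 3x3")
  sub <- img[y0:y1, x0:x1, drop = FALSE]
  structure(
    list(
      gx = conv3_reflect(sub, sobel_x_kernel()),
      gy = conv3_reflect(sub, sobel_y_kernel()),
      roi = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
    ),
    class = "image_gradients"
  )
}

#' Structure-tensor orientation and coherency
#'
#' Builds the local structure tensor (window-smoothed outer product of the
#' Sobel gradients) and derives, per pixel, the feature orientation and the
#' coherency. The feature orientation is the direction of the eigenvector of
#' the *smaller* eigenvalue -- i.e. perpendicular to the dominant gradient,
#' so it runs along edges/channels -- mapped to `[0, 180)` degrees with 90
#' meaning a perfectly vertical channel and 0/180 a horizontal one. Coherency
#' is \eqn{(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)}, 1 for a
#' perfectly oriented texture and defined as 0 where the tensor vanishes
#' (flat regions).
#'
#' @param grad An `"image_gradients"` object from [compute_gradients()].
#' @param window_sigma Gaussian smoothing sigma of the tensor window, pixels.
#'   Default 2. Sigma 0 degenerates to the pointwise tensor, whose coherency
#'   is identically 1 wherever the gradient is nonzero; it is supported but
#'   discouraged.
#' @return A list of class `"orientation_field"` with matrices `angle_deg`
#'   (in `[0, 180)`) and `coherency` (in `[0, 1]`), plus `roi` and
#'   `window_sigma`.
#' @examples
#' img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 90))
#' of <- structure_tensor_orientation(compute_gradients(img))
#' @export
structure_tensor_orientation <- function(grad, window_sigma = 2) {
  stopifnot(inherits(grad, "image_gradients"), window_sigma >= 0)
  gx <- grad$gx; gy <- grad$gy
  jxx <- gaussian_smooth(gx * gx, window_sigma)
  jyy <- gaussian_smooth(gy * gy, window_sigma)
  jxy <- gaussian_smooth(gx * gy, window_sigma)
  # dominant-gradient direction, then +90 deg to get the feature orientation
  theta_g <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  angle <- (theta_g + 90) %% 180
  tr <- jxx + jyy
  lam_diff <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  eps <- 1e-12 * max(tr, 0) + .Machine$double.xmin
  coh <- ifelse(tr > eps, lam_diff / pmax(tr, eps), 0)
  coh <- pmin(pmax(coh, 0), 1)
  structure(
    list(
      angle_deg = matrix(angle, nrow(gx), ncol(gx)),
      coherency = matrix(coh, nrow(gx), ncol(gx)),
      roi = grad$roi, window_sigma = window_sigma
    ),
    class = "orientation_field"
  )
}

#' @export
tidy.orientation_field <- function(x, ...) {
  nr <- nrow(x$angle_deg); nc <- ncol(x$angle_deg)
  tibble(
    x = rep(seq_len(nc), each = nr) + x$roi["x0"] - 1L,
    y = rep(seq_len(nr), times = nc) + x$roi["y0"] - 1L,
    angle_deg = as.vector(x$angle_deg),
    coherency = as.vector(x$coherency)
  )
}

#' Coherency-weighted orientation histogram
#'
#' Accumulates each pixel's coherency as a weight into its orientation bin
#' and normalizes to a probability density per degree (the density integrates
#' to 1 over `[0, 180)`). Pixels with zero coherency contribute nothing, so
#' untextured regions cannot bias the density.
#'
#' @param field An `"orientation_field"` from [structure_tensor_orientation()].
#' @param bin_width_deg Bin width in degrees; must divide 180. Default 1.
#' @return A tibble of class `"orientation_histogram"` with columns
#'   `bin_left`, `bin_mid`, `bin_right`, `weight`, `density`, and attributes
#'   `peak_angle_deg`, `peak_density`, `n_pixels`, `mean_coherency`,
#'   `bin_width_deg`. The reported density is per degree, a convention
#'   recorded in the `density_convention` attribute.
#' @export
coherency_weighted_histogram <- function(field, bin_width_deg = 1) {
  stopifnot(inherits(field, "orientation_field"), bin_width_deg > 0)
  nb <- 180 / bin_width_deg
  if (abs(nb - round(nb)) > 1e-9) abort("bin_width_deg must divide 180 evenly")
  nb <- as.integer(round(nb))
  w <- as.vector(field$coherency)
  a <- as.vector(field$angle_deg)
  total <- sum(w)
  if (total <= 0) {
    abort("untextured ROI: coherency is zero everywhere, no orientation signal")
  }
  idx <- pmin(as.integer(floor(a / bin_width_deg)) + 1L, nb)
  wsum <- vapply(split(w, factor(idx, levels = seq_len(nb))), sum, 0)
  density <- wsum / (total * bin_width_deg)
  edges <- (0:nb) * bin_width_deg
  out <- tibble(
    bin_left = edges[-(nb + 1)], bin_right = edges[-1],
    bin_mid = edges[-(nb + 1)] + bin_width_deg / 2,
    weight = unname(wsum), density = unname(density)
  )
  peak <- which.max(out$density)
  attr(out, "peak_angle_deg") <- out$bin_mid[peak]
  attr(out, "peak_density") <- out$density[peak]
  attr(out, "n_pixels") <- length(a)
  attr(out, "mean_coherency") <- mean(w)
  attr(out, "bin_width_deg") <- bin_width_deg
  attr(out, "density_convention") <- "per_degree_integrates_to_1"
  class(out) <- c("orientation_histogram", class(out))
  out
}

#' Orientation analysis of one image
#'
#' Convenience wrapper chaining [compute_gradients()],
#' [structure_tensor_orientation()] and [coherency_weighted_histogram()].
#'
#' @inheritParams compute_gradients
#' @inheritParams structure_tensor_orientation
#' @inheritParams coherency_weighted_histogram
#' @return An `"orientation_histogram"` tibble.
#' @export
analyze_orientation <- function(img, roi = NULL, window_sigma = 2,
                                bin_width_deg = 1) {
  coherency_weighted_histogram(
    structure_tensor_orientation(compute_gradients(img, roi), window_sigma),
    bin_width_deg
  )
}

#' Summarize peak alignment across replicates
#'
#' Collects the peak orientation of each replicate histogram and reports the
#' mean and standard deviation per group (e.g. bottom/middle/top scaffold
#' position). With a single replicate in a group the SD is reported as `NA`.
#'
#' @param histograms List of `"orientation_histogram"` objects.
#' @param positions Optional character vector (recycled) grouping the
#'   histograms, e.g. `c("bottom", "middle", "top")`.
#' @return Tibble with columns `position`, `n`, `mean_peak_deg`,
#'   `sd_peak_deg`, `mean_peak_density`.
#' @export
summarize_alignment <- function(histograms, positions = NULL) {
  if (length(histograms) == 0L) abort("no histograms supplied")
  peaks <- purrr::map_dbl(histograms, ~ attr(.x, "peak_angle_deg"))
  dens <- purrr::map_dbl(histograms, ~ attr(.x, "peak_density"))
  pos <- if (is.null(positions)) "all" else positions
  tibble(position = rep_len(pos, length(peaks)), peak = peaks, dens = dens) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_peak_deg = mean(.data$peak),
      sd_peak_deg = if (dplyr::n() > 1) stats::sd(.data$peak) else NA_real_,
      mean_peak_density = mean(.data$dens),
      .groups = "drop"
    )
}
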