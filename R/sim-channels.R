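#' Specification for a synthetic aligned-channel texture
#'
#' Describes a longitudinal-cut SEM-like image: a periodic stripe texture at a
#' controlled angle, emulating the aligned micro-channels left by directional
#' ice growth. Angles follow the 0--180 degree convention of the orientation
#' module: 90 degrees is a perfectly vertical channel, 0 (or 180) a perfectly
#' horizontal one.
#'
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param stripe_angle_deg Channel direction in degrees, `[0, 180)`.
#' @param stripe_period Stripe spacing in pixels (>= 2).
#' @param duty_cycle Fraction of the period occupied by the bright phase,
#'   in (0, 1).
#' @param noise_sd Additive Gaussian intensity noise (8-bit units).
#' @param edge_softness Width (pixels) of the smooth stripe edge; 0 gives hard
#'   binary stripes.
#' @param contrast Two intensities `c(low, high)`.
#' @param seed Integer seed.
#' @return A list of class `"channel_field_spec"`.
#' @seealso [gen_channel_field()]
#' @export
channel_field_spec <- function(image_size = c(256L, 256L),
                               stripe_angle_deg = 90,
                               stripe_period = 16,
                               duty_cycle = 0.5,
                               noise_sd = 0,
                               edge_softness = 1,
                               contrast = c(40, 220),
                               seed = 1L) {
  stopifnot(
    length(image_size) == 2L, all(image_size >= 2),
    stripe_angle_deg >= 0, stripe_angle_deg < 180,
    stripe_period >= 2, duty_cycle > 0, duty_cycle < 1,
    noise_sd >= 0, edge_softness >= 0, length(contrast) == 2L
  )
  structure(
    list(
      image_size = as.integer(image_size), stripe_angle_deg = stripe_angle_deg,
      stripe_period = stripe_period, duty_cycle = duty_cycle,
      noise_sd = noise_sd, edge_softness = edge_softness,
      contrast = as.numeric(contrast), seed = as.integer(seed)
    ),
    class = "channel_field_spec"
  )
}

#' Generate a synthetic aligned-channel texture
#'
#' Renders the periodic stripe image described by a [channel_field_spec()].
#' The stripe direction equals `stripe_angle_deg` under the orientation
#' module's convention (x = column, y = row; vertical stripes are 90 degrees).
#' Deterministic given the spec.
#'
#' @param spec A [channel_field_spec()].
#' @return Numeric matrix (0--255 intensities).
#' @examples
#' img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 90))
#' @export
gen_channel_field <- function(spec) {
  stopifnot(inherits(spec, "channel_field_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  th <- spec$stripe_angle_deg * pi / 180
  sth <- sin(th); cth <- cos(th)
  # snap near-zero trig values so axis-aligned stripes are exactly constant
  # along their stripe direction
  if (abs(sth) < 1e-12) sth <- 0
  if (abs(cth) < 1e-12) cth <- 0
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  # phase coordinate perpendicular to the stripe direction (cos th, sin th)
  u <- x * sth - y * cth
  p <- spec$stripe_period
  w <- u - p * floor(u / p)            # wrapped to [0, p)
  on_len <- spec$duty_cycle * p
  # signed distance to the stripe boundary, positive inside the bright phase
  d <- ifelse(w < on_len, pmin(w, on_len - w), -pmin(w - on_len, p - w))
  lo <- spec$contrast[1]; hi <- spec$contrast[2]
  img <- if (spec$edge_softness > 0) {
    lo + (hi - lo) * stats::plogis(d / spec$edge_softness)
  } else {
    lo + (hi - lo) * (d > 0)
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, img + rnorm(length(img), 0, spec$noise_sd))
    img <- pmin(pmax(img, 0), 255)
  }
  matrix(img, nr, nc)
}
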