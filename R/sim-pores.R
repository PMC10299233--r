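#' Specification for a synthetic lamellar pore field
#'
#' Describes a transversal-cut SEM-like image of a freeze-cast scaffold:
#' ovoid (elliptical) pores on a contrasting matrix, with log-normal pore
#' areas and a controlled bounding-box aspect-ratio distribution. The defaults
#' emulate the lamellar microstructure of directionally frozen
#' collagen/chitosan scaffolds: log-normal areas and a mean bounding-box
#' aspect ratio of 0.67 with spread 0.2 (pores taller than wide in the
#' transversal plane).
#'
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param pixel_scale Physical pixel size, micrometres per pixel.
#' @param n_pores Number of pores to place.
#' @param area_meanlog,area_sdlog Log-normal parameters of the true pore area
#'   in square micrometres (mean and sd of `log(area)`).
#' @param aspect_mean,aspect_sd Mean and spread of the bounding-box
#'   width/height ratio (truncated to `(0.05, 20)`).
#' @param orientation_deg Major-axis angle of the ellipses, degrees (0 =
#'   horizontal semi-axis `a` along x).
#' @param allow_overlap If `FALSE` (default) pores are placed by rejection
#'   sampling so that foreground components stay pairwise disjoint with a
#'   2-pixel clearance (8-connected labeling cannot merge neighbours).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (8-bit intensity units).
#' @param polarity `"dark_pores"` (default; dark ellipses on a bright matrix)
#'   or `"bright_pores"`.
#' @param margin_px Clearance enforced between pores when `allow_overlap` is
#'   `FALSE`.
#' @param max_attempts Total placement attempts before the packing is declared
#'   infeasible.
#' @param seed Integer seed; generators are pure functions of their spec.
#' @return A list of class `"pore_field_spec"`.
#' @seealso [gen_pore_field()]
#' @export
pore_field_spec <- function(image_size = c(512L, 512L),
                            pixel_scale = 2,
                            n_pores = 100L,
                            area_meanlog = log(2500),
                            area_sdlog = 0.5,
                            aspect_mean = 0.67,
                            aspect_sd = 0.2,
                            orientation_deg = 0,
                            allow_overlap = FALSE,
                            noise_sd = 0,
                            polarity = c("dark_pores", "bright_pores"),
                            margin_px = 2,
                            max_attempts = 10000L,
                            seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(
    length(image_size) == 2L, all(image_size >= 2),
    pixel_scale > 0, n_pores >= 0, area_sdlog >= 0, aspect_sd >= 0,
    aspect_mean > 0, noise_sd >= 0, margin_px >= 0, max_attempts >= 1
  )
  structure(
    list(
      image_size = as.integer(image_size), pixel_scale = pixel_scale,
      n_pores = as.integer(n_pores), area_meanlog = area_meanlog,
      area_sdlog = area_sdlog, aspect_mean = aspect_mean,
      aspect_sd = aspect_sd, orientation_deg = orientation_deg,
      allow_overlap = isTRUE(allow_overlap), noise_sd = noise_sd,
      polarity = polarity, margin_px = margin_px,
      max_attempts = as.integer(max_attempts), seed = as.integer(seed)
    ),
    class = "pore_field_spec"
  )
}

# Solve ellipse semi-axes (a along orientation, b across) so that the
# axis-aligned bounding box has half-extents with ratio `ratio` = w/h and the
# ellipse area (pixels) equals `area_px`. For a tilted ellipse the bounding
# half-extents are w = sqrt(a^2 c^2 + b^2 s^2), h = sqrt(a^2 s^2 + b^2 c^2).
ellipse_axes_for <- function(area_px, ratio, orientation_deg) {
  cth <- cos(orientation_deg * pi / 180)
  sth <- sin(orientation_deg * pi / 180)
  c2 <- cth^2; s2 <- sth^2
  num <- ratio^2 * c2 - s2
  den <- c2 - ratio^2 * s2
  if (num <= 0 || den <= 0) {
    abort(sprintf(
      "aspect ratio %.3f is not attainable for ellipses oriented at %.1f deg",
      ratio, orientation_deg
    ))
  }
  t <- num / den                       # a^2 / b^2
  b <- sqrt(area_px / (pi * sqrt(t)))
  a <- b * sqrt(t)
  c(a = a, b = b)
}

ellipse_bbox_half <- function(a, b, orientation_deg) {
  cth <- cos(orientation_deg * pi / 180)
  sth <- sin(orientation_deg * pi / 180)
  c(w = unname(sqrt(a^2 * cth^2 + b^2 * sth^2)),
    h = unname(sqrt(a^2 * sth^2 + b^2 * cth^2)))
}

# Pixel coordinates (matrix indices) covered by an ellipse; pixel centres at
# integer coordinates, x = column, y = row.
ellipse_pixels <- function(cx, cy, a, b, orientation_deg, nr, nc, grow = 0) {
  aa <- a + grow; bb <- b + grow
  hb <- ellipse_bbox_half(aa, bb, orientation_deg)
  xr <- max(1L, floor(cx - hb["w"])):min(nc, ceiling(cx + hb["w"]))
  yr <- max(1L, floor(cy - hb["h"])):min(nr, ceiling(cy + hb["h"]))
  if (length(xr) == 0L || length(yr) == 0L) return(cbind(row = integer(), col = integer()))
  cth <- cos(orientation_deg * pi / 180)
  sth <- sin(orientation_deg * pi / 180)
  x <- rep(xr, each = length(yr)) - cx
  y <- rep(yr, times = length(xr)) - cy
  u <- x * cth + y * sth
  v <- -x * sth + y * cth
  inside <- (u / aa)^2 + (v / bb)^2 <= 1
  cbind(row = rep(yr, times = length(xr))[inside],
        col = rep(xr, each = length(yr))[inside])
}

#' Generate a synthetic pore field with ground truth
#'
#' Renders the pore field described by a [pore_field_spec()] and returns both
#' the grayscale image and a per-pore truth table (analytic area, bounding box
#' and aspect ratio, plus the rendering parameters needed to re-rasterize the
#' exact foreground mask). Identical specs give identical output.
#'
#' @param spec A [pore_field_spec()].
#' @return A list of class `"pore_field"` with elements `image` (numeric
#'   matrix, 0--255, with a `pixel_scale` attribute), `truth` (tibble, one row
#'   per pore) and `spec`.
#' @examples
#' pf <- gen_pore_field(pore_field_spec(n_pores = 10, image_size = c(256, 256)))
#' nrow(pf$truth)
#' @export
gen_pore_field <- function(spec) {
  stopifnot(inherits(spec, "pore_field_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  with_seed(spec$seed, {
    bg <- if (spec$polarity == "dark_pores") 220 else 30
    fg <- if (spec$polarity == "dark_pores") 30 else 220
    mask <- matrix(FALSE, nr, nc)
    rows <- vector("list", spec$n_pores)
    rejections <- 0L
    k <- 0L
    while (k < spec$n_pores) {
      if (rejections >= spec$max_attempts) {
        abort(sprintf(
          "infeasible packing: placed %d of %d pores after %d rejected attempts",
          k, spec$n_pores, rejections
        ))
      }
      area_um2 <- exp(rnorm(1, spec$area_meanlog, spec$area_sdlog))
      area_px <- area_um2 / spec$pixel_scale^2
      ratio <- rnorm(1, spec$aspect_mean, spec$aspect_sd)
      if (ratio < 0.05 || ratio > 20) { rejections <- rejections + 1L; next }
      ax <- ellipse_axes_for(area_px, ratio, spec$orientation_deg)
      hb <- ellipse_bbox_half(ax["a"], ax["b"], spec$orientation_deg)
      # keep the ellipse (and its clearance) fully inside the image
      pad <- spec$margin_px + 1.5
      if (2 * hb["w"] + 2 * pad >= nc || 2 * hb["h"] + 2 * pad >= nr) {
        rejections <- rejections + 1L; next
      }
      cx <- runif(1, hb["w"] + pad, nc - hb["w"] - pad)
      cy <- runif(1, hb["h"] + pad, nr - hb["h"] - pad)
      px <- ellipse_pixels(cx, cy, ax["a"], ax["b"], spec$orientation_deg, nr, nc)
      if (nrow(px) == 0L) { rejections <- rejections + 1L; next }
      if (!spec$allow_overlap) {
        grown <- ellipse_pixels(cx, cy, ax["a"], ax["b"], spec$orientation_deg,
                                nr, nc, grow = spec$margin_px)
        if (any(mask[grown])) { rejections <- rejections + 1L; next }
      }
      k <- k + 1L
      mask[px] <- TRUE
      rows[[k]] <- tibble(
        pore_id = k, center_x = cx, center_y = cy,
        semi_a_px = unname(ax["a"]), semi_b_px = unname(ax["b"]),
        orientation_deg = spec$orientation_deg,
        area_um2 = pi * ax["a"] * ax["b"] * spec$pixel_scale^2,
        area_px = nrow(px),
        bbox_width_um = 2 * hb["w"] * spec$pixel_scale,
        bbox_height_um = 2 * hb["h"] * spec$pixel_scale,
        aspect_ratio = unname(hb["w"] / hb["h"])
      )
    }
    truth <- if (spec$n_pores > 0) dplyr::bind_rows(rows) else tibble(
      pore_id = integer(), center_x = double(), center_y = double(),
      semi_a_px = double(), semi_b_px = double(), orientation_deg = double(),
      area_um2 = double(), area_px = integer(), bbox_width_um = double(),
      bbox_height_um = double(), aspect_ratio = double()
    )
    img <- matrix(bg, nr, nc)
    img[mask] <- fg
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
      img <- pmin(pmax(img, 0), 255)
    }
    attr(img, "pixel_scale") <- spec$pixel_scale
    structure(list(image = img, truth = truth, spec = spec),
              class = "pore_field")
  })
}

#' Rasterize a pore truth table into a foreground mask
#'
#' Re-renders the exact foreground mask implied by the truth table of
#' [gen_pore_field()]; with `noise_sd = 0` and non-overlapping pores this
#' reproduces the generated image's pore mask pixel for pixel.
#'
#' @param truth Truth tibble from [gen_pore_field()].
#' @param dim Image dimensions `c(height, width)`.
#' @return Logical matrix, `TRUE` on pore pixels.
#' @export
rasterize_pore_truth <- function(truth, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(truth))) {
    px <- ellipse_pixels(truth$center_x[i], truth$center_y[i],
                         truth$semi_a_px[i], truth$semi_b_px[i],
                         truth$orientation_deg[i], dim[1], dim[2])
    mask[px] <- TRUE
  }
  mask
}
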