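# Internal helpers: seeded evaluation and low-level raster operations shared by
# the simulators, the pore module and the orientation module.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. Every generator routes its randomness through this, so identical
# specs (seed included) give identical outputs regardless of ambient state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Symmetric (mirror, edge pixel repeated) padding by k pixels on every side.
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k >= 1, nr >= 1, nc >= 1)
  ridx <- c(pmin(k:1, nr), seq_len(nr), nr + 1 - pmin(seq_len(k), nr))
  cidx <- c(pmin(k:1, nc), seq_len(nc), nc + 1 - pmin(seq_len(k), nc))
  m[ridx, cidx, drop = FALSE]
}

# 3x3 cross-correlation with reflected borders. `kernel[i, j]` multiplies the
# neighbour at row offset i-2, column offset j-2.
conv3_reflect <- function(m, kernel) {
  stopifnot(all(dim(kernel) == c(3L, 3L)))
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, 1L)
  out <- matrix(0, nr, nc)
  for (i in 1:3) {
    for (j in 1:3) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] * p[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

sobel_x_kernel <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_y_kernel <- function() t(sobel_x_kernel())

# Separable Gaussian smoothing with reflected borders; sigma in pixels.
# sigma <= 0 returns the input unchanged (pointwise structure tensor).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, r)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(w)) {
    tmp <- tmp + w[i] * p[i:(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(w)) {
    out <- out + w[j] * tmp[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Rotate a grayscale image
#'
#' Rotates an image by `angle_deg` about its centre using bilinear
#' interpolation, in the same angular convention as the orientation module
#' (x = column, y = row; a texture oriented at \eqn{\theta} degrees maps to
#' \eqn{\theta + \delta} after rotation by \eqn{\delta}). Pixels sampled from
#' outside the source are set to `fill`.
#'
#' @param img Numeric matrix.
#' @param angle_deg Rotation angle in degrees.
#' @param fill Value for out-of-bounds pixels; defaults to the image mean.
#' @return A numeric matrix of the same dimensions.
#' @export
rotate_gray <- function(img, angle_deg, fill = mean(img)) {
  stopifnot(is.matrix(img), is.numeric(img))
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc) - cy
  # inverse map: source = R(-angle) %*% target
  xs <- cos(th) * x + sin(th) * y + cx
  ys <- -sin(th) * x + cos(th) * y + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get_px <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get_px(y0, x0)
  v01 <- get_px(y0, x0 + 1)
  v10 <- get_px(y0 + 1, x0)
  v11 <- get_px(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  attributes(out) <- attributes(img)[c("dim", "pixel_scale")]
  out
}

# Robust noise-level estimate from second differences; a smooth trend
# contributes only O(step^2) curvature, so densely sampled noise-free curves
# register as (numerically) noiseless while true measurement noise sigma
# gives second differences with standard deviation sigma * sqrt(6).
estimate_noise_sd <- function(x) {
  if (length(x) < 3) return(0)
  d2 <- diff(x, differences = 2)
  median(abs(d2 - median(d2))) / (0.6745 * sqrt(6))
}

# Decision rule shared by segmentation and feature extraction: treat the
# series as noisy when the estimated noise exceeds 0.01% of full scale.
is_noisy <- function(x) estimate_noise_sd(x) > 1e-4 * max(abs(x), 1)

# Centered rolling least-squares slope over an odd window of `w` samples of
# a uniformly spaced series (spacing `step`); edge values replicated.
roll_slope <- function(y, w, step) {
  n <- length(y)
  stopifnot(w %% 2L == 1L, w >= 3L, w <= n)
  i <- seq_len(n)
  cy <- c(0, cumsum(y))
  cxy <- c(0, cumsum(i * y))
  starts <- 1:(n - w + 1L)
  sy <- cy[starts + w] - cy[starts]
  sxy <- cxy[starts + w] - cxy[starts]
  sx <- (starts + (w - 1) / 2) * w
  sxx_c <- w * (w^2 - 1) / 12
  s <- (sxy - sx * sy / w) / sxx_c / step
  half <- (w - 1L) %/% 2L
  c(rep(s[1], half), s, rep(s[length(s)], half))
}

odd_ge <- function(x, lo = 5L) {
  x <- max(as.integer(round(x)), lo)
  if (x %% 2L == 0L) x + 1L else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
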