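test_that("constant images have zero gradients and zero coherency", {
  img <- matrix(100, 32, 32)
  g <- compute_gradients(img)
  expect_true(all(g$gx == 0) && all(g$gy == 0))
  f <- structure_tensor_orientation(g)
  expect_true(all(f$coherency == 0))
  expect_error(coherency_weighted_histogram(f), "untextured")
})

test_that("a linear ramp along x gives constant gx and zero gy", {
  img <- matrix(rep(1:40, each = 30), 30, 40)  # intensity = column index
  g <- compute_gradients(img, roi = c(1, 1, 40, 30))
  interior <- g$gx[3:28, 3:38]
  expect_true(all(abs(interior - 8) < 1e-12))  # sobel weight sum = 8
  expect_true(all(abs(g$gy[3:28, 3:38]) < 1e-12))
})

test_that("transposing the image swaps the gradient components", {
  set.seed(5)
  img <- matrix(runif(900), 30, 30)
  g <- compute_gradients(img, roi = c(1, 1, 30, 30))
  gt <- compute_gradients(t(img), roi = c(1, 1, 30, 30))
  expect_equal(gt$gx, t(g$gy))
  expect_equal(gt$gy, t(g$gx))
})

test_that("roi bounds are validated", {
  img <- matrix(runif(400), 20, 20)
  expect_error(compute_gradients(img, roi = c(1, 1, 25, 20)), "bounds")
  expect_error(compute_gradients(img, roi = c(1, 1, 2, 2)), "3x3")
})

test_that("vertical channels read 90 degrees with coherency 1", {
  img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 90,
                                              noise_sd = 0))
  f <- structure_tensor_orientation(compute_gradients(img))
  textured <- f$coherency > 0.5
  expect_gt(mean(textured), 0.9)
  expect_true(all(abs(f$angle_deg[textured] - 90) < 1))
  expect_gt(mean(f$coherency), 0.99)
  h <- coherency_weighted_histogram(f)
  expect_lt(abs(attr(h, "peak_angle_deg") - 90), 1)
})

test_that("coherency stays in [0, 1] on all fixture types", {
  set.seed(9)
  fixtures <- list(
    gen_channel_field(channel_field_spec(stripe_angle_deg = 37)),
    matrix(runif(128 * 128, 0, 255), 128, 128),
    matrix(7, 64, 64)
  )
  for (img in fixtures) {
    f <- structure_tensor_orientation(compute_gradients(img))
    expect_true(all(f$coherency >= 0 & f$coherency <= 1))
  }
})

test_that("rotating a texture shifts the histogram peak accordingly", {
  base <- 20
  img <- gen_channel_field(channel_field_spec(
    image_size = c(384, 384), stripe_angle_deg = base, stripe_period = 20
  ))
  h0 <- analyze_orientation(img, roi = c(96, 96, 288, 288))
  expect_lt(abs(attr(h0, "peak_angle_deg") - base), 1)
  for (delta in c(15, 30, 45)) {
    rot <- rotate_gray(img, delta)
    h <- analyze_orientation(rot, roi = c(96, 96, 288, 288))
    expected <- (base + delta) %% 180
    diff_deg <- min(abs(attr(h, "peak_angle_deg") - expected),
                    180 - abs(attr(h, "peak_angle_deg") - expected))
    expect_lte(diff_deg, 1)
  }
})

test_that("orientation and coherency are invariant to intensity scaling", {
  img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 63))
  f1 <- structure_tensor_orientation(compute_gradients(img))
  f2 <- structure_tensor_orientation(compute_gradients(img * 3.7))
  expect_equal(f2$angle_deg, f1$angle_deg, tolerance = 1e-9)
  expect_equal(f2$coherency, f1$coherency, tolerance = 1e-9)
})

test_that("histogram density integrates to 1 and respects bin width", {
  img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 135))
  for (bw in c(0.5, 1, 5)) {
    h <- analyze_orientation(img, bin_width_deg = bw)
    expect_equal(sum(h$density * bw), 1, tolerance = 1e-9)
  }
  expect_error(analyze_orientation(img, bin_width_deg = 7), "divide 180")
})

test_that("pure-noise images give a near-flat weighted density", {
  set.seed(12)
  img <- matrix(runif(256 * 256, 0, 255), 256, 256)
  h <- analyze_orientation(img)
  expect_lt(max(h$density), 3 / 180)
})

test_that("symmetric two-angle fields give two equal peaks", {
  f <- structure(
    list(
      angle_deg = matrix(c(rep(45, 50), rep(135, 50)), 10, 10),
      coherency = matrix(1, 10, 10),
      roi = c(x0 = 1, y0 = 1, x1 = 10, y1 = 10), window_sigma = 0
    ),
    class = "orientation_field"
  )
  h <- coherency_weighted_histogram(f, bin_width_deg = 1)
  d45 <- h$density[h$bin_left == 45]
  d135 <- h$density[h$bin_left == 135]
  expect_equal(d45, d135)
  expect_equal(sum(h$density > 0), 2)
})

test_that("sigma = 0 degenerates to the pointwise tensor with unit coherency", {
  img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 90))
  g <- compute_gradients(img)
  f <- structure_tensor_orientation(g, window_sigma = 0)
  nz <- abs(g$gx) + abs(g$gy) > 1e-9
  expect_true(all(f$coherency[nz] == 1))
})

test_that("alignment summaries aggregate peaks per position", {
  mk <- function(peak) {
    h <- tibble::tibble(bin_mid = peak, density = 1)
    attr(h, "peak_angle_deg") <- peak
    attr(h, "peak_density") <- 1
    class(h) <- c("orientation_histogram", class(h))
    h
  }
  s <- summarize_alignment(list(mk(89), mk(90), mk(91)))
  expect_equal(s$mean_peak_deg, 90)
  expect_equal(s$sd_peak_deg, 1)
  single <- summarize_alignment(list(mk(88)))
  expect_true(is.na(single$sd_peak_deg))
  expect_error(summarize_alignment(list()), "no histograms")

  imgs <- lapply(c(1, 2, 3, 4, 5), function(s) {
    gen_channel_field(channel_field_spec(stripe_angle_deg = 90, noise_sd = 15,
                                         seed = s))
  })
  hists <- lapply(imgs, analyze_orientation)
  sm <- summarize_alignment(hists)
  expect_lt(abs(sm$mean_peak_deg - 90), 1)
})
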