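test_that("thresholding a two-level image isolates the dark class", {
  set.seed(1)
  img <- matrix(sample(c(10, 200), 400, replace = TRUE), 20, 20)
  mask <- binarize(img, method = "otsu", polarity = "dark_pores")
  expect_equal(bare(mask), img == 10)
  thr <- attr(mask, "threshold_used")
  expect_true(thr > 10 && thr < 200)
  bright <- binarize(img, method = "fixed", fixed_threshold = 100,
                     polarity = "bright_pores")
  expect_equal(bare(bright), img == 200)
})

test_that("an image with no pore-class pixels yields zero pores downstream", {
  img <- matrix(200, 16, 16); img[1, 1] <- 210  # bright-only content
  mask <- binarize(img, method = "fixed", fixed_threshold = 100)
  labs <- label_components(mask)
  expect_equal(attr(labs, "n_components"), 0L)
  expect_equal(nrow(pore_metrics(labs, pixel_scale = 1)), 0)
})

test_that("constant images make Otsu thresholding fail loudly", {
  expect_error(binarize(matrix(42, 8, 8)), "degenerate")
})

test_that("noise-free synthetic fields binarize to the exact truth mask", {
  pf <- gen_pore_field(pore_field_spec(n_pores = 20, image_size = c(384, 384),
                                       seed = 11))
  mask <- binarize(pf$image)
  expect_equal(bare(mask), rasterize_pore_truth(pf$truth, dim(pf$image)))
})

test_that("labeling matches elementary geometry", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  labs <- label_components(m, 8)
  expect_equal(attr(labs, "n_components"), 1L)
  expect_equal(sum(labs == 1L), 25)

  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(attr(label_components(d, 8), "n_components"), 1L)
  expect_equal(attr(label_components(d, 4), "n_components"), 2L)
})

test_that("labeling agrees with a brute-force flood fill on random masks", {
  set.seed(20)
  for (i in 1:40) {
    m <- random_mask(sample(3:32, 1), sample(3:32, 1), runif(1, 0.2, 0.7))
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      expect_equal(bare(got), oracle_label(m, conn),
                   info = sprintf("mask %d, connectivity %d", i, conn))
    }
  }
})

test_that("component areas conserve the foreground pixel count", {
  set.seed(4)
  m <- random_mask(40, 40, 0.5)
  recs <- pore_metrics(label_components(m, 8), pixel_scale = 1,
                       min_area_px = 0)
  expect_equal(sum(recs$area_px), sum(m))
})

test_that("bounding-box geometry is exact on simple shapes", {
  # 10 px wide x 20 px tall rectangle at scale 1
  m <- matrix(FALSE, 40, 40); m[11:30, 16:25] <- TRUE
  r <- pore_metrics(label_components(m), pixel_scale = 1)
  expect_equal(r$aspect_ratio, 0.5)
  expect_equal(r$area_um2, 200)
  expect_false(r$touches_border)

  # large circle: aspect ratio within 2% of 1 by symmetry
  n <- 101
  cx <- 50.7; cy <- 50.2; rad <- 30
  xs <- matrix(rep(1:n, each = n), n, n); ys <- t(xs)
  circ <- (xs - cx)^2 + (ys - cy)^2 <= rad^2
  rc <- pore_metrics(label_components(circ), pixel_scale = 1)
  expect_lt(abs(rc$aspect_ratio - 1), 0.02)
})

test_that("areas scale with the squared pixel size, aspect ratios do not", {
  pf <- gen_pore_field(pore_field_spec(n_pores = 15, image_size = c(384, 384),
                                       seed = 2))
  labs <- label_components(binarize(pf$image))
  r1 <- pore_metrics(labs, pixel_scale = 1)
  r3 <- pore_metrics(labs, pixel_scale = 3)
  expect_equal(r3$area_um2, 9 * r1$area_um2)
  expect_equal(r3$aspect_ratio, r1$aspect_ratio)
})

test_that("small components are dropped and counted, border pores flagged", {
  m <- matrix(FALSE, 20, 20)
  m[1:4, 1:4] <- TRUE      # border-touching pore
  m[10, 10] <- TRUE        # single-pixel speck
  m[15:17, 12:18] <- TRUE
  recs <- pore_metrics(label_components(m), pixel_scale = 1, min_area_px = 5)
  expect_equal(nrow(recs), 2)
  expect_equal(attr(recs, "dropped_small"), 1L)
  expect_equal(sum(recs$touches_border), 1)
})

test_that("recovered pore geometry matches generator ground truth", {
  pf <- gen_pore_field(recovery_field_spec(40, seed = 21))
  labs <- label_components(binarize(pf$image))
  recs <- pore_metrics(labs, pixel_scale = pf$spec$pixel_scale,
                       min_area_px = 0)
  expect_equal(nrow(recs), 40)
  # map each truth pore to the component under its centre
  lab_at <- labs[cbind(round(pf$truth$center_y), round(pf$truth$center_x))]
  got <- recs[match(lab_at, recs$label), ]
  expect_equal(got$area_px, pf$truth$area_px)
  # rasterized area vs analytic ellipse area: perimeter-proportional bound
  per_um <- pi * (pf$truth$semi_a_px + pf$truth$semi_b_px) *
    pf$spec$pixel_scale
  expect_true(all(abs(got$area_um2 - pf$truth$area_um2) <=
                    2 * per_um * pf$spec$pixel_scale))
  rel_ar <- abs(got$aspect_ratio - pf$truth$aspect_ratio) /
    pf$truth$aspect_ratio
  expect_lt(mean(rel_ar), 0.05)
})

test_that("distributions normalize to unit integral in both binnings", {
  pf <- gen_pore_field(recovery_field_spec(60, seed = 31))
  recs <- analyze_pores(pf$image)
  for (binning in c("linear", "log")) {
    d <- pore_distribution(recs, "area_um2", binning = binning, n_bins = 20)
    widths <- d$bins$bin_right - d$bins$bin_left
    expect_equal(sum(d$bins$density * widths), 1, tolerance = 1e-9)
  }
})

test_that("single-record and degenerate distributions behave", {
  one <- tibble::tibble(area_um2 = 123.4)
  d <- pore_distribution(one, "area_um2")
  expect_equal(sum(d$bins$count), 1)
  widths <- d$bins$bin_right - d$bins$bin_left
  expect_equal(sum(d$bins$density * widths), 1, tolerance = 1e-9)

  same <- tibble::tibble(aspect_ratio = rep(0.7, 25))
  ds <- pore_distribution(same, "aspect_ratio")
  expect_equal(ds$summary$q3 - ds$summary$q1, 0)

  expect_error(pore_distribution(tibble::tibble(area_um2 = double()),
                                 "area_um2"), "no pores")
})

test_that("log-binned area distributions refit the generating log-normal", {
  mu <- log(800); sg <- 0.5
  set.seed(77)
  recs <- tibble::tibble(area_um2 = exp(rnorm(10000, mu, sg)))
  d <- pore_distribution(recs, "area_um2", binning = "log", n_bins = 40)
  expect_equal(sum(d$bins$density * (d$bins$bin_right - d$bins$bin_left)), 1,
               tolerance = 1e-9)
  refit <- lognormal_summary(recs$area_um2)
  expect_lt(abs(refit$log_mean - mu), 3 * sg / sqrt(10000))
})
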