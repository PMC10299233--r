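#' Binarize a grayscale micrograph
#'
#' Converts an intensity image into a pore mask by global thresholding, the
#' first step of the transversal-cut pore analysis. The threshold is either
#' computed by Otsu's method on a 256-level histogram or supplied by the user;
#' the value actually used is recorded for the analysis report.
#'
#' @param img Numeric matrix of intensities.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold intensity; required (and only allowed)
#'   with `method = "fixed"`.
#' @param polarity `"dark_pores"` (pixels strictly below the threshold are
#'   pores, the SEM default where pore lumens are dark) or `"bright_pores"`
#'   (strictly above).
#' @return Logical matrix (`TRUE` = pore) with attributes `threshold_used`,
#'   `method` and `polarity`.
#' @examples
#' pf <- gen_pore_field(pore_field_spec(n_pores = 5, image_size = c(128, 128)))
#' mask <- binarize(pf$image)
#' attr(mask, "threshold_used")
#' @export
binarize <- function(img, method = c("otsu", "fixed"), fixed_threshold = NULL,
                     polarity = c("dark_pores", "bright_pores")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(img), is.numeric(img), nrow(img) >= 2, ncol(img) >= 2)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) abort("method = 'fixed' requires fixed_threshold")
    thr <- fixed_threshold
  } else {
    if (!is.null(fixed_threshold)) {
      abort("fixed_threshold is only meaningful with method = 'fixed'")
    }
    rng <- range(img)
    if (diff(rng) == 0) {
      abort("degenerate threshold: image is constant, Otsu's method is undefined")
    }
    thr <- EBImage::otsu(img, range = rng, levels = 256)
  }
  mask <- if (polarity == "dark_pores") img < thr else img > thr
  attr(mask, "threshold_used") <- as.numeric(thr)
  attr(mask, "method") <- method
  attr(mask, "polarity") <- polarity
  mask
}

#' Label connected pore components
#'
#' Uniquely labels the connected foreground regions of a binary mask under
#' 4- or 8-connectivity. Labels are contiguous `1..K` in order of first
#' (column-major) occurrence, so the output is deterministic and equivalent to
#' any correct two-pass or flood-fill labeling. Internally the foreground
#' pixel-adjacency graph is built and its connected components extracted with
#' \pkg{igraph}.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return Integer matrix of labels (0 = background) with attributes
#'   `connectivity` and `n_components`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(label_components(m, 8))  # 1: diagonal pixels connect
#' max(label_components(m, 4))  # 2
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask),
            connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  nfg <- sum(mask)
  out <- matrix(0L, nr, nc)
  if (nfg > 0L) {
    ids <- matrix(0L, nr, nc)
    ids[mask] <- seq_len(nfg)
    pair <- function(a, b) {
      sel <- a > 0L & b > 0L
      cbind(a[sel], b[sel])
    }
    edges <- rbind(
      pair(ids[, -nc, drop = FALSE], ids[, -1, drop = FALSE]),   # right
      pair(ids[-nr, , drop = FALSE], ids[-1, , drop = FALSE])    # down
    )
    if (connectivity == 8 && nr > 1L && nc > 1L) {
      edges <- rbind(
        edges,
        pair(ids[-nr, -nc, drop = FALSE], ids[-1, -1, drop = FALSE]),  # down-right
        pair(ids[-nr, -1, drop = FALSE], ids[-1, -nc, drop = FALSE])   # down-left
      )
    }
    g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
    if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    out[mask] <- match(memb, unique(memb))  # renumber by first occurrence
  }
  attr(out, "connectivity") <- as.integer(connectivity)
  attr(out, "n_components") <- if (nfg > 0L) max(out) else 0L
  out
}

#' Per-pore geometry from a label map
#'
#' Extracts, for every labeled component, the physical area (pixel count
#' scaled by the squared pixel size), the axis-aligned bounding box, the
#' aspect ratio (bounding-box width divided by height, which may exceed 1),
#' and whether the component touches the image border. Components smaller
#' than `min_area_px` pixels are dropped; the number dropped is reported in
#' the `dropped_small` attribute. The retained row count is the pore count.
#'
#' @param labels Integer label matrix from [label_components()].
#' @param pixel_scale Pixel size, micrometres per pixel.
#' @param min_area_px Minimum component size in pixels (default 5 suppresses
#'   single-pixel noise; 0 disables).
#' @return Tibble with one row per retained pore: `label`, `area_px`,
#'   `area_um2`, `bbox_width_um`, `bbox_height_um`, `aspect_ratio`,
#'   `touches_border`.
#' @export
pore_metrics <- function(labels, pixel_scale, min_area_px = 5) {
  stopifnot(is.matrix(labels), pixel_scale > 0, min_area_px >= 0)
  nr <- nrow(labels); nc <- ncol(labels)
  fg <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    out <- tibble(
      label = integer(), area_px = integer(), area_um2 = double(),
      bbox_width_um = double(), bbox_height_um = double(),
      aspect_ratio = double(), touches_border = logical()
    )
    attr(out, "dropped_small") <- 0L
    attr(out, "pixel_scale") <- pixel_scale
    return(out)
  }
  recs <- tibble(
    label = labels[fg], row = fg[, 1], col = fg[, 2]
  ) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area_px = dplyr::n(),
      rmin = min(.data$row), rmax = max(.data$row),
      cmin = min(.data$col), cmax = max(.data$col),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      area_um2 = .data$area_px * pixel_scale^2,
      bbox_width_um = (.data$cmax - .data$cmin + 1L) * pixel_scale,
      bbox_height_um = (.data$rmax - .data$rmin + 1L) * pixel_scale,
      aspect_ratio = .data$bbox_width_um / .data$bbox_height_um,
      touches_border = .data$rmin == 1L | .data$cmin == 1L |
        .data$rmax == nr | .data$cmax == nc
    )
  dropped <- sum(recs$area_px < min_area_px)
  recs <- recs |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::select(
      "label", "area_px", "area_um2", "bbox_width_um", "bbox_height_um",
      "aspect_ratio", "touches_border"
    )
  attr(recs, "dropped_small") <- as.integer(dropped)
  attr(recs, "pixel_scale") <- pixel_scale
  recs
}

#' Normalized discrete distribution of a pore variable
#'
#' Bins a per-pore variable into a normalized density (the density integrates
#' to 1 over the binned axis) for comparison across experimental conditions,
#' and returns the boxplot summary (median, quartiles, whiskers) used in the
#' standard presentation of pore area and aspect-ratio results.
#'
#' @param records Pore tibble from [pore_metrics()] (or any data frame).
#' @param variable Name of the numeric column to summarize, e.g. `"area_um2"`
#'   or `"aspect_ratio"`.
#' @param binning `"linear"` or `"log"` (log-spaced bin edges; requires
#'   positive values).
#' @param n_bins Number of bins.
#' @return A list of class `"pore_distribution"`: `bins` (tibble with
#'   `bin_left`, `bin_mid`, `bin_right`, `count`, `density`), `summary`
#'   (one-row tibble with n, mean, sd, median, quartiles, whiskers),
#'   `variable`, `binning`.
#' @export
pore_distribution <- function(records, variable = "area_um2",
                              binning = c("linear", "log"), n_bins = 30) {
  binning <- match.arg(binning)
  stopifnot(is.data.frame(records), variable %in% names(records), n_bins >= 1)
  x <- records[[variable]]
  if (length(x) == 0L) abort("no pores: cannot build a distribution from zero records")
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (binning == "log" && any(x <= 0)) abort("log binning requires positive values")
  rng <- range(x)
  if (diff(rng) == 0) {
    # single point mass: one unit-integral bin around the value
    half <- max(abs(rng[1]) * 5e-3, 0.5)
    edges <- c(rng[1] - half, rng[1] + half)
  } else if (binning == "log") {
    edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
    edges[length(edges)] <- rng[2]
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  h <- graphics::hist(x, breaks = edges, plot = FALSE, include.lowest = TRUE,
                      right = FALSE)
  widths <- diff(edges)
  bins <- tibble(
    bin_left = edges[-length(edges)], bin_right = edges[-1],
    bin_mid = h$mids, count = h$counts,
    density = h$counts / (length(x) * widths)
  )
  bs <- grDevices::boxplot.stats(x)
  summary <- tibble(
    n = length(x), mean = mean(x), sd = stats::sd(x),
    whisker_low = bs$stats[1], q1 = bs$stats[2], median = bs$stats[3],
    q3 = bs$stats[4], whisker_high = bs$stats[5]
  )
  structure(
    list(bins = bins, summary = summary, variable = variable,
         binning = binning),
    class = "pore_distribution"
  )
}

#' @export
print.pore_distribution <- function(x, ...) {
  cat(sprintf(
    "<pore_distribution> %s (%s binning): n = %d, median = %.4g, IQR = [%.4g, %.4g]\n",
    x$variable, x$binning, x$summary$n, x$summary$median, x$summary$q1,
    x$summary$q3
  ))
  invisible(x)
}

#' Run the full pore analysis on one image
#'
#' Convenience wrapper chaining [binarize()], [label_components()] and
#' [pore_metrics()].
#'
#' @inheritParams binarize
#' @inheritParams pore_metrics
#' @param connectivity Passed to [label_components()].
#' @param pixel_scale Micrometres per pixel; defaults to the image's
#'   `pixel_scale` attribute.
#' @return The pore tibble from [pore_metrics()], with attributes
#'   `threshold_used` and `connectivity` added.
#' @export
analyze_pores <- function(img, pixel_scale = attr(img, "pixel_scale"),
                          method = c("otsu", "fixed"), fixed_threshold = NULL,
                          polarity = c("dark_pores", "bright_pores"),
                          connectivity = 8, min_area_px = 5) {
  if (is.null(pixel_scale)) {
    abort("pixel_scale is required (it is never assumed from image metadata)")
  }
  mask <- binarize(img, method = method, fixed_threshold = fixed_threshold,
                   polarity = polarity)
  labs <- label_components(mask, connectivity = connectivity)
  recs <- pore_metrics(labs, pixel_scale = pixel_scale,
                       min_area_px = min_area_px)
  attr(recs, "threshold_used") <- attr(mask, "threshold_used")
  attr(recs, "connectivity") <- attr(labs, "connectivity")
  recs
}
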