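#' Read a grayscale micrograph
#'
#' Reads a TIFF or PNG image as a numeric matrix of 8-bit-scale intensities
#' (0--255). Multi-channel images are averaged to grayscale. The physical
#' pixel scale is never guessed from file metadata and must be supplied.
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @param pixel_scale Micrometres per pixel, attached as an attribute.
#' @return Numeric matrix with attributes `pixel_scale` and `source`.
#' @export
read_gray_image <- function(path, pixel_scale) {
  stopifnot(file.exists(path), pixel_scale > 0)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(
    ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  img <- arr * 255
  attr(img, "pixel_scale") <- pixel_scale
  attr(img, "source") <- path
  img
}

#' Write a grayscale image
#'
#' Writes a numeric matrix (0--255 intensity scale) as 8-bit grayscale TIFF
#' or PNG, chosen by file extension.
#'
#' @param img Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  x <- pmin(pmax(img / 255, 0), 1)
  attributes(x) <- list(dim = dim(x))
  ext <- tolower(tools::file_ext(path))
  switch(
    ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  invisible(path)
}

#' Read a traction-test log
#'
#' Reads a comma-separated traction log with columns `time_s`,
#' `displacement_mm`, `force_N`.
#'
#' @param path CSV file.
#' @return Tibble with the three columns.
#' @export
read_traction_log <- function(path) {
  stopifnot(file.exists(path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "displacement_mm", "force_N")
  if (!all(need %in% names(out))) {
    abort(sprintf("traction log must have columns %s", paste(need, collapse = ", ")))
  }
  out[need]
}

#' Read a freeze-casting temperature log
#'
#' Reads a comma-separated log with columns `time_s`, `temp_C`.
#'
#' @param path CSV file.
#' @return Tibble with the two columns.
#' @export
read_ramp_log <- function(path) {
  stopifnot(file.exists(path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "temp_C") %in% names(out))) {
    abort("ramp log must have columns time_s, temp_C")
  }
  out[c("time_s", "temp_C")]
}
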