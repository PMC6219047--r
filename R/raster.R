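# Pixel-level preprocessing: RGB frame -> binary reagent mask.
#
# Images are plain base-R containers: a height x width numeric matrix for a
# single channel, or a height x width x 3 array for RGB, with 8-bit values in
# [0, 255], row-major with the origin at the top-left (row 1 = top scan line).
# Binary masks are height x width integer matrices of 0/1.

assert_raster <- function(img, channels = NULL, arg = "img") {
  if (!is.numeric(img) || !(is.matrix(img) || (is.array(img) && length(dim(img)) == 3L))) {
    abort(sprintf("`%s` must be a numeric matrix (1 channel) or a 3-d array (RGB).", arg))
  }
  d <- dim(img)
  nch <- if (length(d) == 2L) 1L else d[3L]
  if (!nch %in% c(1L, 3L)) {
    abort(sprintf("`%s` must have 1 or 3 channels, not %d.", arg, nch))
  }
  if (!is.null(channels) && nch != channels) {
    abort(sprintf("`%s` must have %d channel(s), not %d.", arg, channels, nch))
  }
  if (d[1L] < 1L || d[2L] < 1L) abort(sprintf("`%s` must be at least 1 x 1.", arg))
  rng <- range(img)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255) {
    abort(sprintf("`%s` intensities must lie in [0, 255] with no missing values.", arg))
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.numeric(mask) || !is.matrix(mask)) {
    abort(sprintf("`%s` must be a numeric 0/1 matrix.", arg))
  }
  if (!all(mask == 0L | mask == 1L)) {
    abort(sprintf("`%s` may contain only 0 and 1.", arg))
  }
  invisible(mask)
}

#' Rectangular region of interest
#'
#' The camera and tip holder are rigidly mounted, so the sub-rectangle of the
#' frame containing the tip (and, separately, the holder) is known a priori.
#' Bounds are 1-based and inclusive, following R matrix indexing.
#'
#' @param top,bottom First and last row of the region.
#' @param left,right First and last column of the region.
#' @return A `roi_spec` list with fields `top`, `bottom`, `left`, `right`.
#' @examples
#' roi_spec(45, 315, 5, 315)
#' @export
roi_spec <- function(top, bottom, left, right) {
  for (v in list(top = top, bottom = bottom, left = left, right = right)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v)) {
      abort("ROI bounds must be single integer values.")
    }
  }
  if (top < 1L) abort("ROI `top` must be >= 1.")
  if (left < 1L) abort("ROI `left` must be >= 1.")
  if (bottom < top) abort("ROI is empty: `bottom` is above `top`.")
  if (right < left) abort("ROI is empty: `right` is left of `left`.")
  structure(
    list(top = as.integer(top), bottom = as.integer(bottom),
         left = as.integer(left), right = as.integer(right)),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> rows %d..%d, cols %d..%d\n", x$top, x$bottom, x$left, x$right))
  invisible(x)
}

#' Crop a region of interest out of an image
#'
#' @param img A single- or 3-channel raster image.
#' @param roi An [roi_spec()].
#' @return The sub-image, same channel count as the input.
#' @examples
#' img <- matrix(1:16, 4, 4)
#' crop_roi(img, roi_spec(2, 3, 2, 3))
#' @export
crop_roi <- function(img, roi) {
  assert_raster(img)
  if (!inherits(roi, "roi_spec")) abort("`roi` must be created with roi_spec().")
  d <- dim(img)
  if (roi$bottom > d[1L]) abort(sprintf("ROI `bottom` (%d) exceeds image height (%d).", roi$bottom, d[1L]))
  if (roi$right > d[2L]) abort(sprintf("ROI `right` (%d) exceeds image width (%d).", roi$right, d[2L]))
  if (length(d) == 2L) {
    img[roi$top:roi$bottom, roi$left:roi$right, drop = FALSE]
  } else {
    img[roi$top:roi$bottom, roi$left:roi$right, , drop = FALSE]
  }
}

#' Luminance of an RGB image
#'
#' ITU-R BT.601 weighted sum, `Y = 0.299 R + 0.587 G + 0.114 B`, rounded
#' half-up to the nearest integer. This is the standard luma for 8-bit video
#' sensors such as the smartphone camera module the method targets.
#'
#' @param img A 3-channel raster image.
#' @return A single-channel image of the same height and width.
#' @export
luminance <- function(img) {
  assert_raster(img, channels = 3L)
  y <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  pmin(floor(y + 0.5), 255)
}

#' Pure-red image
#'
#' Colour-difference channel that isolates a red reagent from a grey matte
#' background: `P = max(R - Y, 0)` per pixel, where `Y` is the BT.601
#' luminance. Grey pixels (R = G = B) map exactly to 0; saturated red maps
#' close to 179, so a single fixed threshold separates reagent from
#' background. Set `sign = "y_minus_r"` to flip the difference if a device's
#' imagery requires the opposite convention.
#'
#' @param img A 3-channel raster image.
#' @param sign Which difference to take; default `"r_minus_y"`.
#' @return A single-channel image of the same height and width.
#' @export
pure_red <- function(img, sign = c("r_minus_y", "y_minus_r")) {
  sign <- match.arg(sign)
  assert_raster(img, channels = 3L)
  y <- luminance(img)
  d <- if (sign == "r_minus_y") img[, , 1L] - y else y - img[, , 1L]
  pmin(pmax(d, 0), 255)
}

shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w), drop = FALSE]
}

sort3 <- function(a, b, c) {
  lo <- pmin(a, b, c)
  hi <- pmax(a, b, c)
  list(lo = lo, mid = a + b + c - lo - hi, hi = hi)
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood, removing the
#' salt-and-pepper specks that survive fixed-threshold segmentation. Borders
#' are handled by edge replication so the output has the input's shape.
#'
#' The median of nine is computed exactly with a vectorised min/max network
#' (sort the three rows of the window, then take the median of the maximum of
#' the lows, the median of the mids, and the minimum of the highs).
#'
#' @param img A single-channel raster image.
#' @return The filtered image, same shape.
#' @export
median3x3 <- function(img) {
  assert_raster(img, channels = 1L)
  r1 <- sort3(shift_replicate(img, -1L, -1L), shift_replicate(img, -1L, 0L), shift_replicate(img, -1L, 1L))
  r2 <- sort3(shift_replicate(img, 0L, -1L), img, shift_replicate(img, 0L, 1L))
  r3 <- sort3(shift_replicate(img, 1L, -1L), shift_replicate(img, 1L, 0L), shift_replicate(img, 1L, 1L))
  sort3(pmax(r1$lo, r2$lo, r3$lo), pmax(pmin(r1$mid, r2$mid), pmin(r1$mid, r3$mid), pmin(r2$mid, r3$mid)),
        pmin(r1$hi, r2$hi, r3$hi))$mid
}

#' Fixed-threshold binarisation
#'
#' A pixel is foreground (1) iff its intensity is strictly greater than the
#' threshold. A fixed threshold is sufficient because the device controls
#' illumination and uses a matte background, so the pure-red intensities of
#' reagent and background are far apart.
#'
#' @param img A single-channel raster image.
#' @param threshold Scalar in `[0, 255]`.
#' @return An integer 0/1 matrix of the same shape.
#' @examples
#' binarize(matrix(c(10, 40, 41, 200), 2, 2), 40)
#' @export
binarize <- function(img, threshold) {
  assert_raster(img, channels = 1L)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255) {
    abort("`threshold` must be a single value in [0, 255].")
  }
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > threshold] <- 1L
  mask
}

#' Read an 8-bit image file
#'
#' PNG is read with the png package; TIFF with the tiff package; JPEG through
#' EBImage when available. Values are rescaled to `[0, 255]`; an alpha channel
#' is dropped; greyscale files come back as a matrix.
#'
#' @param path Path to a `.png`, `.tif(f)` or `.jpe?g` file.
#' @return A raster image (matrix or H x W x 3 array) of 8-bit intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("Reading TIFF requires the tiff package.")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) abort("Reading JPEG requires the EBImage package.")
      x <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x,y(,channel); transpose back to row = scan line
      if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
    },
    abort(sprintf("Unsupported image extension '.%s' (use png, tiff or jpeg).", ext))
  )
  if (length(dim(raw)) == 3L && dim(raw)[3L] == 4L) raw <- raw[, , 1:3, drop = FALSE]
  if (length(dim(raw)) == 3L && dim(raw)[3L] == 1L) raw <- raw[, , 1L]
  img <- floor(raw * 255 + 0.5)
  assert_raster(img)
  img
}

#' Write an image as 8-bit PNG
#'
#' @param img A raster image with intensities in `[0, 255]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_raster(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
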