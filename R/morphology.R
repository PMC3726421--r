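#' Grayscale erosion / dilation by a flat disk
#'
#' Flat morphological erosion (pointwise minimum) or dilation (maximum) over
#' a discrete Euclidean disk of the given radius, with replicate padding at
#' the image border so no artificial extrema are introduced.
#'
#' @param img numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return numeric matrix of the same dimensions.
#' @export
erode_disk <- function(img, radius) {
  assert_image(img)
  check_se_radius(img, radius)
  cpp_morph_disk(img, as.integer(radius), FALSE)
}

#' @rdname erode_disk
#' @export
dilate_disk <- function(img, radius) {
  assert_image(img)
  check_se_radius(img, radius)
  cpp_morph_disk(img, as.integer(radius), TRUE)
}

check_se_radius <- function(img, radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 1)
    stopf("radius must be a single value >= 1")
  if (radius > min(dim(img)) / 2)
    stopf("radius %d exceeds half the image extent (%dx%d)",
          as.integer(radius), nrow(img), ncol(img))
}

#' Grayscale reconstruction
#'
#' `reconstruct_dilation(marker, mask)` is the morphological grayscale
#' reconstruction by dilation of `marker` under `mask` (`marker <= mask`);
#' `reconstruct_erosion` is its dual for `marker >= mask`. Both use
#' 8-connectivity and a hybrid raster-scan/queue algorithm.
#'
#' @param marker,mask numeric matrices of equal dimensions.
#' @return numeric matrix.
#' @export
reconstruct_dilation <- function(marker, mask) {
  assert_image(marker, "marker")
  assert_image(mask, "mask")
  cpp_reconstruct_dilation(marker, mask)
}

#' @rdname reconstruct_dilation
#' @export
reconstruct_erosion <- function(marker, mask) {
  assert_image(marker, "marker")
  assert_image(mask, "mask")
  -cpp_reconstruct_dilation(-marker, -mask)
}

#' Opening / closing by reconstruction
#'
#' Opening by reconstruction erodes with a disk of the given radius and then
#' reconstructs by dilation under the original image; it removes bright
#' structures in which the disk does not fit while exactly preserving the
#' contours of the survivors. Closing by reconstruction is the dual and
#' removes small dark structures.
#'
#' @inheritParams erode_disk
#' @return numeric matrix; `reconstruct_open(x) <= x <= reconstruct_close(x)`
#'   pixelwise.
#' @export
reconstruct_open <- function(img, radius) {
  reconstruct_dilation(erode_disk(img, radius), img)
}

#' @rdname reconstruct_open
#' @export
reconstruct_close <- function(img, radius) {
  reconstruct_erosion(dilate_disk(img, radius), img)
}

#' Plain morphological closing by a disk
#'
#' @inheritParams erode_disk
#' @export
close_disk <- function(img, radius) {
  erode_disk(dilate_disk(img, radius), radius)
}

#' Simplify a hematoxylin image at one scale
#'
#' Applies opening by reconstruction then closing by reconstruction, both
#' with a disk of radius `n`, followed by a plain morphological closing with
#' a disk of half that radius (rounded to the nearest integer). The sequence
#' flattens structures smaller than the scale of interest and removes thin
#' protrusions without displacing the main nuclear contours. Larger `n`
#' targets larger nuclei; dark objects whose width is below the disk
#' diameter are erased entirely, which is what restricts each scale to its
#' own nucleus size range.
#'
#' @param hema grayscale hematoxylin image (nuclei dark), numeric matrix.
#' @param n scale: disk radius in pixels (>= 2).
#' @return numeric matrix with attribute `scale = n`.
#' @export
preprocess_at_scale <- function(hema, n) {
  assert_image(hema, "hematoxylin image")
  if (n < 2) stopf("scale n must be >= 2")
  out <- reconstruct_open(hema, n)
  out <- reconstruct_close(out, n)
  out <- close_disk(out, max(1L, as.integer(round(n / 2))))
  attr(out, "scale") <- as.integer(n)
  out
}

#' h-minima transform
#'
#' Grayscale reconstruction by erosion of `img + h` over `img`; suppresses
#' every regional minimum whose depth is less than `h` while leaving the
#' image unchanged elsewhere (up to raising basin floors by at most `h`).
#'
#' @param img numeric matrix.
#' @param h non-negative suppression depth, in the image's intensity units.
#' @return numeric matrix, pixelwise `>= img` and `<= img + h`.
#' @export
h_minima_transform <- function(img, h) {
  assert_image(img)
  if (length(h) != 1L || is.na(h) || h < 0) stopf("h must be a single value >= 0")
  if (h == 0) return(img)
  reconstruct_erosion(img + h, img)
}

#' Regional and extended regional minima
#'
#' `regional_minima()` labels the 8-connected flat zones that have no lower
#' neighbor. `extended_regional_minima()` labels the regional minima of the
#' h-minima transform, i.e. only basins at least `h` deep survive.
#'
#' @param img numeric matrix.
#' @param h depth parameter (> 0 for extended minima).
#' @return integer matrix of component labels (0 = not a minimum).
#' @export
regional_minima <- function(img) {
  assert_image(img)
  cpp_regional_minima(img)
}

#' @rdname regional_minima
#' @export
extended_regional_minima <- function(img, h) {
  if (length(h) != 1L || is.na(h) || h <= 0) stopf("h must be a single value > 0")
  regional_minima(h_minima_transform(img, h))
}

#' Morphological skeleton of a binary mask
#'
#' Thins the mask to a (mostly) 1-pixel-wide skeleton while preserving the
#' connectivity of every foreground component; the skeleton is a subset of
#' the mask.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
skeletonize <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
    mask <- mask > 0
  }
  cpp_thin(mask)
}
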