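#' Extract nucleus markers from a symmetry map
#'
#' Foreground markers are the extended regional minima (depth `h`) of the
#' normalized symmetry map, in which nucleus centers are dark basins. A
#' constant map carries no symmetry information and yields no markers.
#'
#' @param sym a `symmetry_map` from [frst_orientation_only()], or a numeric
#'   matrix already normalized to \[0, 1\] with centers as minima.
#' @param h basin depth on the normalized scale (default 0.4).
#' @return integer matrix of labeled foreground markers (0 = background).
#' @export
extract_frst_markers <- function(sym, h = 0.4) {
  img <- if (inherits(sym, "symmetry_map")) sym$s else sym
  assert_image(img, "symmetry map")
  if (diff(range(img)) < 1e-12)
    return(matrix(0L, nrow(img), ncol(img)))
  extended_regional_minima(img, h)
}

#' Extract regional-minima markers from a preprocessed image
#'
#' Foreground markers are the regional minima of the morphologically
#' simplified image. Minima plateaus touching the image border and plateaus
#' larger than the maximal nucleus area at the scale (`4 n^2 pi`) are
#' excluded; the latter also removes the degenerate whole-image minimum of a
#' flat tile.
#'
#' @param pre preprocessed image at scale `n` (see [preprocess_at_scale()]).
#' @param n the scale the image was preprocessed at; taken from the image's
#'   `scale` attribute when missing.
#' @return integer matrix of labeled foreground markers.
#' @export
extract_minima_markers <- function(pre, n = attr(pre, "scale")) {
  assert_image(pre, "preprocessed image")
  if (is.null(n)) stopf("scale n is required (no 'scale' attribute found)")
  lab <- regional_minima(pre)
  k <- max(lab)
  if (k == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  drop <- sort(unique(c(border[border > 0L], which(sizes > 4 * n^2 * pi))))
  relabel_components(lab, drop)
}

# drop the given label ids and renumber the rest consecutively
relabel_components <- function(lab, drop) {
  k <- max(lab)
  if (k == 0L) return(lab)
  map <- seq_len(k)
  map[drop] <- 0L
  keep <- map > 0L
  map[keep] <- seq_len(sum(keep))
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Build the background marker for a marker set
#'
#' Assumes each foreground marker corresponds to a nucleus of the maximal
#' size at the current scale (radius `2n`, the largest radius in the FRST
#' set), dilates the markers accordingly, and uses the morphological
#' skeleton of the complement as the background marker. The skeleton is
#' guaranteed disjoint from the dilated foreground.
#'
#' @param markers labeled foreground marker matrix (at least one marker).
#' @param n scale in pixels.
#' @return logical matrix: thin background marker skeleton.
#' @export
build_background_marker <- function(markers, n) {
  if (!is.matrix(markers)) stopf("markers must be a matrix")
  if (max(markers) < 1) stopf("at least one foreground marker is required")
  fg <- markers > 0
  dil <- cpp_binary_dilate_disk(fg, 2 * n)
  bg_map <- !dil
  if (!any(bg_map))
    stopf("foreground markers too dense for scale %d: background map is empty", n)
  skeletonize(bg_map)
}

#' Assemble a validated marker set
#'
#' @param foreground labeled foreground marker matrix.
#' @param background logical background marker mask, disjoint from the
#'   foreground and non-empty.
#' @param marker_type `"frst"` or `"minima"`.
#' @param scale the preprocessing scale `n`.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(foreground, background, marker_type = c("frst", "minima"),
                       scale) {
  marker_type <- match.arg(marker_type)
  if (!identical(dim(foreground), dim(background)))
    stopf("foreground and background dimensions differ")
  if (!any(background)) stopf("background marker is empty")
  if (any(background & foreground > 0))
    stopf("foreground and background markers overlap")
  structure(list(foreground = foreground, background = background,
                 marker_type = marker_type, scale = as.integer(scale)),
            class = "marker_set")
}

#' Impose regional minima at marker locations
#'
#' Reconstruction-based minima imposition: the only regional minima of the
#' result are the marker pixels. Marker pixels are forced to a level below
#' the global minimum and the modified image is reconstructed by erosion
#' over it.
#'
#' @param f segmentation function (e.g. a gradient magnitude image).
#' @param mask logical matrix of marker pixels.
#' @return numeric matrix whose regional minima coincide with `mask`.
#' @export
impose_minima <- function(f, mask) {
  assert_image(f)
  if (!is.logical(mask) || !identical(dim(mask), dim(f)))
    stopf("mask must be a logical matrix matching f")
  if (!any(mask)) stopf("marker mask is empty")
  lo <- min(f) - 1
  hi <- max(f) + 1
  fm <- matrix(hi, nrow(f), ncol(f))
  fm[mask] <- lo
  g <- pmin(f + 1, fm)  # marker image >= mask image, equality on markers
  reconstruct_erosion(fm, g)
}

#' Marker-controlled watershed segmentation
#'
#' Computes the Sobel gradient magnitude of the preprocessed image, imposes
#' regional minima at the foreground and background marker locations, and
#' floods it with a seeded watershed. The region grown from the background
#' marker is discarded; every foreground marker yields exactly one region.
#'
#' @param pre preprocessed image (numeric matrix).
#' @param markers a [marker_set()].
#' @return integer label matrix (`watershed_labels`): one positive label per
#'   foreground marker, 0 on ridges and background, with attributes `scale`
#'   and `marker_type`.
#' @export
watershed_with_markers <- function(pre, markers) {
  assert_image(pre, "preprocessed image")
  if (!inherits(markers, "marker_set")) stopf("markers must be a marker_set")
  if (!identical(dim(markers$foreground), dim(pre)))
    stopf("marker and image dimensions differ")
  grad <- sobel_magnitude(pre)
  fg <- markers$foreground
  nfg <- max(fg)
  bglab <- nfg + 1L
  seeds <- fg
  seeds[markers$background] <- bglab
  imposed <- impose_minima(grad, seeds > 0)
  lab <- cpp_watershed(imposed, seeds)
  lab[lab == bglab] <- 0L
  attr(lab, "scale") <- markers$scale
  attr(lab, "marker_type") <- markers$marker_type
  class(lab) <- c("watershed_labels", class(lab))
  lab
}

#' @export
print.watershed_labels <- function(x, ...) {
  cat(sprintf("watershed label map %dx%d: %d regions (scale %s, %s markers)\n",
              nrow(x), ncol(x), max(x),
              attr(x, "scale") %||% "?", attr(x, "marker_type") %||% "?"))
  invisible(x)
}
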