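#' Stain absorption vectors for Lambert-Beer unmixing
#'
#' Builds the 3x3 matrix of per-channel (R, G, B) optical-density absorption
#' coefficients used to unmix an H&E tile into hematoxylin, eosin and a
#' residual channel. Columns are normalized to unit Euclidean norm; a missing
#' residual column is completed as the normalized cross product of the
#' hematoxylin and eosin columns, which makes the matrix invertible whenever
#' the two stain vectors are linearly independent.
#'
#' The defaults are the standard published H&E absorption coefficients
#' (hematoxylin approximately (0.65, 0.70, 0.29) and eosin approximately
#' (0.07, 0.99, 0.11) before normalization).
#'
#' @param hematoxylin,eosin numeric length-3 RGB absorption coefficients
#'   (non-negative, not all zero).
#' @param residual optional length-3 residual column; computed from the cross
#'   product when `NULL`.
#' @param i0 per-channel background (white) intensity, recycled to length 3.
#' @return An object of class `stain_vectors`: list with `M` (3x3 matrix,
#'   rows = RGB, columns = hematoxylin/eosin/residual) and `i0`.
#' @examples
#' sv <- stain_vectors()
#' round(crossprod(sv$M)[1, 1], 6)  # unit-norm columns
#' @export
stain_vectors <- function(hematoxylin = c(0.65, 0.70, 0.29),
                          eosin = c(0.07, 0.99, 0.11),
                          residual = NULL,
                          i0 = 255) {
  norm3 <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) != 3L) stopf("%s must have length 3", what)
    if (any(v < 0)) stopf("%s coefficients must be non-negative", what)
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stopf("%s vector is zero", what)
    v / n
  }
  h <- norm3(hematoxylin, "hematoxylin")
  e <- norm3(eosin, "eosin")
  if (is.null(residual)) {
    r <- c(h[2] * e[3] - h[3] * e[2],
           h[3] * e[1] - h[1] * e[3],
           h[1] * e[2] - h[2] * e[1])
    if (sqrt(sum(r^2)) < 1e-8)
      stopf("hematoxylin and eosin columns are collinear; cannot complete residual")
    r <- abs(r) / sqrt(sum(r^2))
  } else {
    r <- norm3(residual, "residual")
  }
  M <- cbind(hematoxylin = h, eosin = e, residual = r)
  rownames(M) <- c("R", "G", "B")
  if (abs(det(M)) < 1e-8)
    stopf("stain matrix is singular (columns '%s' are linearly dependent)",
          paste(colnames(M), collapse = "', '"))
  i0 <- rep_len(as.numeric(i0), 3L)
  if (any(i0 <= 0)) stopf("background intensity i0 must be positive")
  structure(list(M = M, i0 = i0), class = "stain_vectors")
}

#' @export
print.stain_vectors <- function(x, ...) {
  cat("Stain absorption vectors (unit-norm columns)\n")
  print(round(x$M, 4))
  cat("background intensity i0:", paste(round(x$i0, 2), collapse = ", "), "\n")
  invisible(x)
}

assert_tile <- function(tile) {
  if (!(is.array(tile) && length(dim(tile)) == 3L && dim(tile)[3] == 3L))
    stopf("tile must be an h x w x 3 RGB array (got %s)",
          paste(dim(tile), collapse = "x"))
  if (min(tile) < 0 || max(tile) > 255)
    stopf("tile values must lie in [0, 255]")
  invisible(tile)
}

#' Convert an RGB tile to optical density
#'
#' Applies the Lambert-Beer relation per channel:
#' `OD = -log10(max(I, eps) / I0)` with `eps = I0/255`, so saturated-black
#' pixels map to the finite ceiling `-log10(1/255)` and background white maps
#' to zero. Negative densities (pixels brighter than `I0`) are clipped to 0.
#'
#' @param tile h x w x 3 RGB array with values in \[0, 255\].
#' @param i0 per-channel background intensity (positive, recycled to 3).
#' @return h x w x 3 array of non-negative optical densities.
#' @export
rgb_to_optical_density <- function(tile, i0 = 255) {
  assert_tile(tile)
  i0 <- rep_len(as.numeric(i0), 3L)
  if (any(i0 <= 0)) stopf("i0 must be positive")
  od <- tile
  for (ch in 1:3) {
    eps <- i0[ch] / 255
    od[, , ch] <- -log10(pmax(tile[, , ch], eps) / i0[ch])
  }
  od[od < 0] <- 0
  od
}

#' Unmix optical densities into per-stain concentrations
#'
#' Solves the 3x3 linear system `M c = OD` at every pixel and clips negative
#' concentrations to zero.
#'
#' @param od h x w x 3 optical-density array (see [rgb_to_optical_density()]).
#' @param vectors a [stain_vectors()] object.
#' @param clip clip negative concentrations to 0 (default `TRUE`).
#' @return list with matrices `hematoxylin`, `eosin`, `residual`.
#' @export
unmix_stains <- function(od, vectors = stain_vectors(), clip = TRUE) {
  if (!inherits(vectors, "stain_vectors")) stopf("vectors must be stain_vectors")
  if (!(is.array(od) && length(dim(od)) == 3L && dim(od)[3] == 3L))
    stopf("od must be an h x w x 3 array")
  d <- dim(od)
  Minv <- solve(vectors$M)
  flat <- matrix(od, ncol = 3L)          # pixels x channels
  conc <- flat %*% t(Minv)               # pixels x stains
  if (clip) conc[conc < 0] <- 0
  out <- lapply(1:3, function(j) matrix(conc[, j], d[1], d[2]))
  names(out) <- colnames(vectors$M)
  out
}

# luminance weights used when collapsing the re-rendered single-stain RGB
# image to grayscale (ITU-R BT.601)
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Grayscale hematoxylin single-stain image
#'
#' Unmixes the tile, re-renders an RGB image from the hematoxylin
#' concentration alone through the Lambert-Beer forward model, and collapses
#' it to grayscale with standard luminance weights. Nuclei (high hematoxylin)
#' come out dark; zero concentration everywhere yields a uniform image at the
#' background luminance.
#'
#' @inheritParams unmix_stains
#' @param tile h x w x 3 RGB array in \[0, 255\].
#' @param concentration_map if `TRUE`, also return the raw hematoxylin
#'   concentration matrix as attribute `"concentration"`.
#' @return numeric matrix in \[0, 255\] (8-bit levels, nuclei dark).
#' @export
hematoxylin_image <- function(tile, vectors = stain_vectors(),
                              concentration_map = FALSE) {
  assert_tile(tile)
  conc <- unmix_stains(rgb_to_optical_density(tile, vectors$i0), vectors)
  ch <- conc$hematoxylin
  img <- render_stain_gray(ch, vectors$M[, "hematoxylin"], vectors$i0)
  if (concentration_map) attr(img, "concentration") <- ch
  img
}

# forward Lambert-Beer rendering of one stain to 8-bit grayscale luminance
render_stain_gray <- function(conc, column, i0 = rep(255, 3)) {
  lum <- matrix(0, nrow(conc), ncol(conc))
  for (chn in 1:3)
    lum <- lum + LUMA_WEIGHTS[chn] * i0[chn] * 10^(-column[chn] * conc)
  img <- round(lum)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

# forward Lambert-Beer rendering of H+E concentration fields to an 8-bit
# RGB tile (shared by the synthetic generator and round-trip tests)
render_he_tile <- function(h_conc, e_conc, vectors = stain_vectors()) {
  d <- dim(h_conc)
  tile <- array(0, c(d[1], d[2], 3))
  M <- vectors$M
  for (chn in 1:3) {
    od <- M[chn, "hematoxylin"] * h_conc + M[chn, "eosin"] * e_conc
    tile[, , chn] <- round(vectors$i0[chn] * 10^(-od))
  }
  tile[tile < 0] <- 0
  tile[tile > 255] <- 255
  tile
}
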