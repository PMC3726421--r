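# Reading tiles and writing segmentation artifacts.

#' Read an RGB tile from PNG or TIFF
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return h x w x 3 numeric array with values in \[0, 255\].
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use png/tif/tiff)", ext))
  if (length(dim(img)) == 2L) stopf("tile must have 3 channels, got grayscale")
  if (dim(img)[3] > 3L) img <- img[, , 1:3]  # drop alpha
  if (dim(img)[3] != 3L) stopf("tile must have 3 channels, got %d", dim(img)[3])
  img * 255
}

#' Write / read a 16-bit label mask (TIFF)
#'
#' Label maps are stored as 16-bit grayscale TIFF, value = label id.
#'
#' @param labels integer matrix (values 0..65535).
#' @param path output path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stopf("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read the accepted-ellipse table
#'
#' CSV columns: `id, center_x, center_y, semi_major, semi_minor,
#' orientation_rad, scale_n, marker_type, solidity`; pixel coordinates are
#' 0-based with x = column, y = row.
#'
#' @param result a `nucseg_result` or its `ellipses` data frame.
#' @param path output path.
#' @export
write_ellipses_csv <- function(result, path) {
  df <- if (inherits(result, "nucseg_result")) result$ellipses else result
  out <- data.frame(id = seq_len(nrow(df)),
                    center_x = df$cx, center_y = df$cy,
                    semi_major = df$a, semi_minor = df$b,
                    orientation_rad = df$theta,
                    scale_n = df$scale, marker_type = df$marker_type,
                    solidity = df$fitness)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ellipses_csv
#' @export
read_ellipses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(cx = df$center_x, cy = df$center_y, a = df$semi_major,
             b = df$semi_minor, theta = df$orientation_rad,
             scale = df$scale_n, marker_type = df$marker_type,
             fitness = df$solidity, stringsAsFactors = FALSE)
}

#' Write an RGB tile as PNG
#'
#' @param tile h x w x 3 array in \[0, 255\].
#' @param path output path.
#' @export
write_tile <- function(tile, path) {
  png::writePNG(tile / 255, path)
  invisible(path)
}
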