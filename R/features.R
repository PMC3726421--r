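# Region features (solidity, boundary saliency, mass displacement, area),
# rule-based rejection and ellipse standardization.

# second central moments of a pixel set, with the 1/12 pixel-extent term so
# a filled disk of radius r has minor/major semi-axes r.
region_moments <- function(rows, cols) {
  n <- length(rows)
  cx <- mean(cols); cy <- mean(rows)
  dx <- cols - cx; dy <- rows - cy
  rxx <- sum(dx * dx) / n
  ryy <- sum(dy * dy) / n
  rxy <- sum(dx * dy) / n
  # raw (uncorrected) smallest eigenvalue flags collinear pixel sets
  rtr <- rxx + ryy
  rdisc <- sqrt(max(0, (rtr / 2)^2 - (rxx * ryy - rxy * rxy)))
  l2_raw <- rtr / 2 - rdisc
  mxx <- rxx + 1 / 12   # pixel-extent term: a filled disk of radius r
  myy <- ryy + 1 / 12   # then has semi-axes exactly r
  mxy <- rxy
  tr <- mxx + myy
  det <- mxx * myy - mxy * mxy
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  if (theta < 0) theta <- theta + pi
  if (theta >= pi) theta <- theta - pi
  list(cx = cx, cy = cy, mxx = mxx, myy = myy, mxy = mxy,
       l1 = l1, l2 = l2, l2_raw = l2_raw, theta = theta,
       major = 2 * sqrt(l1), minor = 2 * sqrt(max(l2, 0)))
}

# "convex area" in the conventional region-properties sense: the number of
# pixels whose centers fall inside (or on) the convex hull of the region's
# pixel centers; >= pixel count, so solidity <= 1
convex_hull_area <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(n)
  # boundary pixels (those missing a 4-neighbor) via a padded crop mask
  r0 <- min(rows) - 2L; c0 <- min(cols) - 2L   # 1-px border on every side
  snr <- max(rows) - r0 + 1L; snc <- max(cols) - c0 + 1L
  m <- matrix(FALSE, snr, snc)
  rr <- rows - r0; cc <- cols - c0
  m[cbind(rr, cc)] <- TRUE
  inside <- m[cbind(rr + 1L, cc)] & m[cbind(rr - 1L, cc)] &
            m[cbind(rr, cc + 1L)] & m[cbind(rr, cc - 1L)]
  bx <- cols[!inside]; by <- rows[!inside]
  if (length(bx) < 3L) { bx <- cols; by <- rows }
  # hull over the pixel edge midpoints (the +-0.5 axis offsets), then count
  # pixel centers inside it — the standard region-properties convention:
  # strictly below 1 for curved boundaries, ~0.95 for a discrete disk
  px <- c(bx - 0.5, bx + 0.5, bx, bx)
  py <- c(by, by, by - 0.5, by + 0.5)
  hull <- chull(px, py)
  k <- length(hull)
  if (k < 3L) return(n)
  hx <- px[hull]; hy <- py[hull]
  # rasterize the hull: count grid points satisfying every half-plane
  gx <- matrix(min(cols):max(cols), nrow = max(rows) - min(rows) + 1L,
               ncol = max(cols) - min(cols) + 1L, byrow = TRUE)
  gy <- matrix(min(rows):max(rows), nrow = nrow(gx), ncol = ncol(gx))
  # chull returns vertices clockwise in (x, y); orient via the shoelace sign
  j <- c(2:k, 1)
  orient <- sign(sum(hx * hy[j] - hx[j] * hy))
  ok <- matrix(TRUE, nrow(gx), ncol(gx))
  for (i in seq_len(k)) {
    ex <- hx[j[i]] - hx[i]; ey <- hy[j[i]] - hy[i]
    cr <- ex * (gy - hy[i]) - ey * (gx - hx[i])
    ok <- ok & (orient * cr >= -1e-9)
  }
  max(n, sum(ok))
}

#' Compute the rejection features of a watershed region
#'
#' Measures, on the preprocessed image the region was segmented from:
#' solidity `s` (pixel count over convex-hull area), boundary saliency `l`
#' (median intensity in a tight band outside the region minus the median in
#' a band just inside; large and positive for a dark object on a brighter
#' surround), mass displacement `d` (distance between the centroid and the
#' inverse-intensity-weighted centroid, normalized by the minor axis length
#' of the region's moment ellipse), and the pixel area.
#'
#' @param idx integer vector of linear (column-major) pixel indices.
#' @param pre numeric matrix the region was segmented from.
#' @param band_width width in pixels of the inner/outer intensity bands.
#' @return list with `s`, `l` (`NA` when the outer band is empty, e.g. a
#'   region covering the whole frame), `d`, `area`.
#' @export
compute_region_features <- function(idx, pre, band_width = 3) {
  assert_image(pre)
  if (length(idx) == 0L) stopf("region is empty")
  nr <- nrow(pre); nc <- ncol(pre)
  rc <- idx_to_rc(idx, nr)
  rows <- rc[, 1L]; cols <- rc[, 2L]
  area <- length(idx)

  s <- min(1, area / convex_hull_area(rows, cols))

  # bands from a padded bounding-box crop
  bw <- as.integer(band_width)
  r0 <- max(1L, min(rows) - bw); r1 <- min(nr, max(rows) + bw)
  c0 <- max(1L, min(cols) - bw); c1 <- min(nc, max(cols) + bw)
  snr <- r1 - r0 + 1L; snc <- c1 - c0 + 1L
  sub <- matrix(0, snr, snc)
  sidx <- rc_to_idx(rows - r0 + 1L, cols - c0 + 1L, snr)
  sub[sidx] <- 1
  radius_ok <- bw <= min(snr, snc) / 2
  if (radius_ok) {
    dil <- cpp_morph_disk(sub, bw, TRUE) > 0
    ero <- cpp_morph_disk(sub, bw, FALSE) > 0
  } else {  # degenerate sliver; fall back to the mask itself
    dil <- sub > 0
    ero <- matrix(FALSE, snr, snc)
  }
  mask <- sub > 0
  outer_band <- dil & !mask
  inner_band <- mask & !ero
  crop <- pre[r0:r1, c0:c1, drop = FALSE]
  l <- if (any(outer_band) && any(inner_band))
    median(crop[outer_band]) - median(crop[inner_band]) else NA_real_

  mom <- region_moments(rows, cols)
  w <- 256 - pre[idx]
  wx <- sum(w * cols) / sum(w)
  wy <- sum(w * rows) / sum(w)
  disp <- sqrt((mom$cx - wx)^2 + (mom$cy - wy)^2)
  d <- if (mom$minor > 0) disp / mom$minor else Inf

  list(s = s, l = l, d = d, area = area)
}

#' Rule-based rejection of candidate regions
#'
#' Keeps a region iff all four features fall in the probable ranges:
#' solidity in (0.875, 1), boundary saliency in (20, 255), mass displacement
#' in \[0, 0.08\], and area within \[n^2 pi, 4 n^2 pi\] for the scale `n`
#' the region was segmented at. Regions with an undefined saliency are
#' rejected.
#'
#' @param features data frame with columns `s`, `l`, `d`, `area` (one row
#'   per region).
#' @param n scale at which the regions were segmented.
#' @param ranges feature ranges; see [nucseg_config()].
#' @return logical vector: `TRUE` for accepted rows.
#' @export
filter_candidates <- function(features, n,
                              ranges = list(s = c(0.875, 1), l = c(20, 255),
                                            d = c(0, 0.08))) {
  if (nrow(features) == 0L) return(logical(0))
  with(features,
       !is.na(s) & s > ranges$s[1] & s < ranges$s[2] &
       !is.na(l) & l > ranges$l[1] & l < ranges$l[2] &
       !is.na(d) & d >= ranges$d[1] & d <= ranges$d[2] &
       area >= n^2 * pi & area <= 4 * n^2 * pi)
}

#' Standardize a region as an ellipse
#'
#' Fits the ellipse with the same normalized second central moments as the
#' pixel set (the moment ellipse). Orientation is the angle of the major
#' axis against the x (column) axis, in \[0, pi).
#'
#' @param idx linear pixel indices of the region (>= 5 pixels).
#' @param nr number of image rows (to decode the indices).
#' @param fitness fitness value to attach (by convention the region's
#'   solidity).
#' @return object of class `ellipse_region`: list with `cx`, `cy` (0-based
#'   pixel coordinates, x = column, y = row), semi-axes `a >= b`, `theta`,
#'   `fitness`.
#' @export
fit_ellipse <- function(idx, nr, fitness = NA_real_) {
  if (length(idx) < 5L) stopf("ellipse fit needs at least 5 pixels")
  rc <- idx_to_rc(idx, nr)
  mom <- region_moments(rc[, 1L], rc[, 2L])
  if (mom$l2_raw <= 1e-9) stopf("degenerate (collinear) region: cannot fit ellipse")
  structure(list(cx = mom$cx - 1, cy = mom$cy - 1,
                 a = mom$major, b = mom$minor,
                 theta = mom$theta, fitness = fitness),
            class = "ellipse_region")
}

#' Rasterize an ellipse to pixel indices
#'
#' @param e an `ellipse_region`, or a list with `cx`, `cy` (0-based), `a`,
#'   `b`, `theta`.
#' @param dims image dimensions `c(nrow, ncol)`.
#' @return integer vector of linear pixel indices (column-major, 1-based).
#' @export
rasterize_ellipse <- function(e, dims) {
  nr <- dims[1L]; nc <- dims[2L]
  ct <- cos(e$theta); st <- sin(e$theta)
  ex <- sqrt((e$a * ct)^2 + (e$b * st)^2)
  ey <- sqrt((e$a * st)^2 + (e$b * ct)^2)
  c0 <- max(1L, floor(e$cx + 1 - ex)); c1 <- min(nc, ceiling(e$cx + 1 + ex))
  r0 <- max(1L, floor(e$cy + 1 - ey)); r1 <- min(nr, ceiling(e$cy + 1 + ey))
  if (c1 < c0 || r1 < r0) return(integer(0))
  cs <- c0:c1; rs <- r0:r1
  dx <- matrix(cs - (e$cx + 1), length(rs), length(cs), byrow = TRUE)
  dy <- matrix(rs - (e$cy + 1), length(rs), length(cs))
  u <- (dx * ct + dy * st) / e$a
  v <- (-dx * st + dy * ct) / e$b
  sel <- which(u * u + v * v <= 1)
  if (length(sel) == 0L) return(integer(0))
  rr <- rs[((sel - 1L) %% length(rs)) + 1L]
  cc <- cs[((sel - 1L) %/% length(rs)) + 1L]
  rc_to_idx(rr, cc, nr)
}

#' @export
print.ellipse_region <- function(x, ...) {
  cat(sprintf("ellipse at (%.1f, %.1f), a=%.1f b=%.1f theta=%.2f fitness=%.3f\n",
              x$cx, x$cy, x$a, x$b, x$theta, x$fitness))
  invisible(x)
}
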