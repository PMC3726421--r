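# Brute-force oracles (independent of the package's C++ implementations)
# and small fixture builders shared across the test files.

# out[r, c] = m[r + dr, c + dc], `pad` outside the frame
shift_mat <- function(m, dr, dc, pad) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

o_dilate3 <- function(m) {
  out <- m
  for (k in 1:8) out <- pmax(out, shift_mat(m, NB8[k, 1], NB8[k, 2], -Inf))
  out
}

# geodesic reconstruction by dilation: iterate 3x3 dilation clipped by mask
o_reconstruct_dil <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    J2 <- pmin(o_dilate3(J), mask)
    if (identical(J2, J)) return(J)
    J <- J2
  }
}

o_reconstruct_ero <- function(marker, mask) {
  -o_reconstruct_dil(-marker, -mask)
}

o_hminima <- function(img, h) o_reconstruct_ero(img + h, img)

# regional-minima mask by fixpoint propagation of the "not a minimum" flag
# across equal-valued plateaus
o_regional_minima_mask <- function(img) {
  notmin <- matrix(FALSE, nrow(img), ncol(img))
  for (k in 1:8)
    notmin <- notmin | (shift_mat(img, NB8[k, 1], NB8[k, 2], Inf) < img)
  repeat {
    prev <- notmin
    for (k in 1:8) {
      nv <- shift_mat(img, NB8[k, 1], NB8[k, 2], Inf)
      nn <- shift_mat(notmin, NB8[k, 1], NB8[k, 2], FALSE)
      notmin <- notmin | (nv == img & nn)
    }
    if (identical(notmin, prev)) break
  }
  !notmin
}

# connected-component labeling through igraph (independent of cpp_label)
o_label <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  offs <- if (conn == 8) list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
          else list(c(-1, 0), c(0, -1))
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  efrom <- integer(0); eto <- integer(0)
  for (o in offs) {
    qr <- rr + o[1]; qc <- cc + o[2]
    ok <- qr >= 1 & qr <= nr & qc >= 1 & qc <= nc
    nidx <- (qc - 1L) * nr + qr
    j <- match(nidx, idx)
    keep <- ok & !is.na(j)
    efrom <- c(efrom, which(keep))
    eto <- c(eto, j[keep])
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_along(idx)]
  lab[idx] <- as.integer(memb)
  lab
}

o_regional_minima <- function(img) o_label(o_regional_minima_mask(img))

# canonical relabeling by first occurrence in column-major scan order, so two
# labelings of the same partition compare equal
canon_labels <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  f <- factor(lab[idx], levels = unique(lab[idx]))
  out <- lab
  out[idx] <- as.integer(f)
  out
}

o_dice <- function(x, y) 2 * length(intersect(x, y)) / (length(x) + length(y))
o_overlap <- function(x, y)
  length(intersect(x, y)) / min(length(x), length(y))

# fixtures ------------------------------------------------------------------

# paint a filled disk of value `fg` onto `img`
paint_disk <- function(img, cy, cx, r, fg) {
  d <- -r:r
  msk <- outer(d^2, d^2, `+`) <= r^2
  ys <- cy + d; xs <- cx + d
  sub <- img[ys, xs]
  sub[msk] <- fg
  img[ys, xs] <- sub
  img
}

rand_img <- function(nr, nc, levels = 6) {
  matrix(sample.int(levels, nr * nc, replace = TRUE), nr, nc) * 1.0
}

rand_idx_set <- function(n, npix) sort(sample.int(npix, n))
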