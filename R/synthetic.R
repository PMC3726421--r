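# Seeded synthetic H&E tile generator. Nuclei are rendered as elliptical
# hematoxylin-dominant absorbers through the same Lambert-Beer forward model
# the unmixing inverts, over an eosin-textured stroma, with optional
# lymphocyte-like and junk distractors. Ground truth (label mask + ellipse
# table) is emitted alongside.

#' Specification for a synthetic H&E tile
#'
#' Difficulty presets: `"easy"` (well-separated nuclei, low chromatin
#' noise, no distractors), `"medium"` (30% of nuclei placed touching a
#' neighbor, moderate noise, lymphocyte-like and junk distractors) and
#' `"hard"` (50% clustered, strong marginalized chromatin: brighter
#' interior with a dark rim, more distractors). Any field can be overridden
#' explicitly.
#'
#' @param preset difficulty preset.
#' @param size tile side in pixels.
#' @param n_nuclei number of epithelial nuclei.
#' @param minor_range range of nucleus minor semi-axes in pixels (matches
#'   the default preprocessing scale set 10..18).
#' @param minor_pop optional vector of minor semi-axis population centers
#'   (sampled with +-0.5 px jitter) for bimodal size experiments; overrides
#'   `minor_range`.
#' @param aspect_range range of major/minor axis ratios.
#' @param cluster_frac fraction of nuclei placed touching a neighbor.
#' @param chromatin_sd multiplicative chromatin noise amplitude.
#' @param rim_strength marginalized-chromatin rim contrast (0 = none).
#' @param n_lymphocytes,n_junk distractor counts (small dark disks of
#'   radius < 8 px; faint elongated junk particles).
#' @param hema_level,eosin_level stain concentration levels.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(preset = c("easy", "medium", "hard"),
                       size = 512, n_nuclei = 40,
                       minor_range = c(10, 18), minor_pop = NULL,
                       aspect_range = c(1.0, 1.5),
                       cluster_frac = NULL, chromatin_sd = NULL,
                       rim_strength = NULL, n_lymphocytes = NULL,
                       n_junk = NULL,
                       hema_level = 0.65, eosin_level = 0.35,
                       seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    easy   = list(cluster_frac = 0.0, chromatin_sd = 0.05, rim_strength = 0,
                  n_lymphocytes = 0L, n_junk = 0L),
    medium = list(cluster_frac = 0.3, chromatin_sd = 0.12, rim_strength = 0,
                  n_lymphocytes = 6L, n_junk = 8L),
    hard   = list(cluster_frac = 0.5, chromatin_sd = 0.15, rim_strength = 0.5,
                  n_lymphocytes = 10L, n_junk = 12L))
  spec <- list(
    preset = preset, size = as.integer(size), n_nuclei = as.integer(n_nuclei),
    minor_range = minor_range, minor_pop = minor_pop,
    aspect_range = aspect_range,
    cluster_frac = cluster_frac %||% def$cluster_frac,
    chromatin_sd = chromatin_sd %||% def$chromatin_sd,
    rim_strength = rim_strength %||% def$rim_strength,
    n_lymphocytes = as.integer(n_lymphocytes %||% def$n_lymphocytes),
    n_junk = as.integer(n_junk %||% def$n_junk),
    hema_level = hema_level, eosin_level = eosin_level,
    seed = as.integer(seed))
  if (spec$n_nuclei < 0L) stopf("n_nuclei must be >= 0")
  if (diff(range(spec$minor_range)) < 0 || min(spec$minor_range) <= 0)
    stopf("minor_range must be a positive, non-degenerate range")
  structure(spec, class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("synthetic tile spec: %s, %dx%d px, %d nuclei, seed %d\n",
              x$preset, x$size, x$size, x$n_nuclei, x$seed))
  invisible(x)
}

# ellipse radius along absolute direction phi
ellipse_radius <- function(a, b, theta, phi) {
  a * b / sqrt((b * cos(phi - theta))^2 + (a * sin(phi - theta))^2)
}

# band-limited standard-normal noise field
smooth_noise <- function(nr, nc, sigma = 6) {
  z <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), sigma)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic H&E tile with ground truth
#'
#' Samples non-identical ellipses with rejection (non-clustered nuclei do
#' not overlap; clustered nuclei touch a neighbor with marginal overlap),
#' builds hematoxylin and eosin concentration fields, and renders the RGB
#' tile via `I = I0 * 10^(-M c)`. Pixels claimed by two touching nuclei are
#' assigned to the nearer one in the normalized ellipse metric, so the
#' label mask partitions the nuclei.
#'
#' @param spec a [synth_spec()].
#' @param vectors stain vectors used for the forward rendering.
#' @return object of class `synth_tile`: list with `tile` (h x w x 3 RGB in
#'   \[0, 255\]), `labels` (integer ground-truth mask), `nuclei` (data frame
#'   `id, cx, cy, a, b, theta, area_px`; coordinates 0-based, x = column)
#'   and `spec`.
#' @export
generate_tile <- function(spec, vectors = stain_vectors()) {
  if (!inherits(spec, "synth_spec")) stopf("spec must be a synth_spec")
  with_seed(spec$seed, generate_tile_impl(spec, vectors))
}

generate_tile_impl <- function(spec, vectors) {
  sz <- spec$size
  n <- spec$n_nuclei
  P <- list(cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
            theta = numeric(0))
  sep_gap <- 4    # minimum boundary gap between non-clustered nuclei
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(400)) {
      b <- if (!is.null(spec$minor_pop))
        sample(spec$minor_pop, 1L) + runif(1, -0.5, 0.5)
      else runif(1, spec$minor_range[1], spec$minor_range[2])
      aspect <- runif(1, spec$aspect_range[1], spec$aspect_range[2])
      a <- b * aspect
      theta <- runif(1, 0, pi)
      margin <- a + 8
      clustered <- i > 1L && runif(1) < spec$cluster_frac
      if (clustered) {
        j <- sample(length(P$cx), 1L)
        phi <- runif(1, 0, 2 * pi)
        dtouch <- ellipse_radius(a, b, theta, phi + pi) +
                  ellipse_radius(P$a[j], P$b[j], P$theta[j], phi)
        cx <- P$cx[j] + 0.98 * dtouch * cos(phi)
        cy <- P$cy[j] + 0.98 * dtouch * sin(phi)
      } else {
        j <- 0L
        cx <- runif(1, margin, sz - margin)
        cy <- runif(1, margin, sz - margin)
      }
      if (cx < margin || cx > sz - margin || cy < margin || cy > sz - margin)
        next
      ok <- TRUE
      for (k in seq_along(P$cx)) {
        if (k == j) next
        dd <- sqrt((cx - P$cx[k])^2 + (cy - P$cy[k])^2)
        if (dd < a + P$a[k] + sep_gap) { ok <- FALSE; break }
      }
      if (!ok) next
      P$cx <- c(P$cx, cx); P$cy <- c(P$cy, cy)
      P$a <- c(P$a, a); P$b <- c(P$b, b); P$theta <- c(P$theta, theta)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("infeasible packing: could not place nucleus %d of %d in a %dx%d frame",
            i, n, sz, sz)
  }

  # ground-truth labels; overlap pixels go to the nearer nucleus in the
  # normalized ellipse metric
  lab <- matrix(0L, sz, sz)
  ndist <- matrix(Inf, sz, sz)
  rims <- vector("list", n)
  for (i in seq_len(n)) {
    e <- list(cx = P$cx[i], cy = P$cy[i], a = P$a[i], b = P$b[i],
              theta = P$theta[i])
    px <- rasterize_ellipse(e, c(sz, sz))
    rc <- idx_to_rc(px, sz)
    dx <- (rc[, 2L] - 1) - e$cx; dy <- (rc[, 1L] - 1) - e$cy
    ct <- cos(e$theta); st <- sin(e$theta)
    u <- (dx * ct + dy * st) / e$a
    v <- (-dx * st + dy * ct) / e$b
    nd <- u * u + v * v
    take <- nd < ndist[px]
    lab[px[take]] <- i
    ndist[px[take]] <- nd[take]
    rims[[i]] <- px[nd > 0.7]   # outer shell, for marginalized chromatin
  }

  # hematoxylin concentration field
  chrom <- smooth_noise(sz, sz, sigma = 3)
  haze <- smooth_noise(sz, sz, sigma = 8)
  H <- 0.03 + 0.015 * pmin(pmax(haze, -2), 2)
  nuc_px <- which(lab > 0L)
  H[nuc_px] <- spec$hema_level *
    pmax(1 + spec$chromatin_sd * chrom[nuc_px], 0.3)
  if (spec$rim_strength > 0) {
    for (i in seq_len(n)) {
      rim <- rims[[i]][lab[rims[[i]]] == i]
      core <- setdiff(which(lab == i), rim)
      H[core] <- H[core] * (1 - 0.35 * spec$rim_strength)
      H[rim] <- H[rim] * (1 + 0.6 * spec$rim_strength)
    }
  }

  # distractors: small dark lymphocyte-like disks and faint elongated junk
  place_clear <- function(r_eff) {
    for (att in seq_len(200)) {
      cx <- runif(1, r_eff + 2, sz - r_eff - 2)
      cy <- runif(1, r_eff + 2, sz - r_eff - 2)
      clear <- TRUE
      for (k in seq_along(P$cx)) {
        if (sqrt((cx - P$cx[k])^2 + (cy - P$cy[k])^2) < P$a[k] + r_eff + 3) {
          clear <- FALSE; break
        }
      }
      if (clear) return(c(cx, cy))
    }
    NULL
  }
  for (q in seq_len(spec$n_lymphocytes)) {
    r <- runif(1, 4, 7)
    pos <- place_clear(r)
    if (is.null(pos)) next
    px <- rasterize_ellipse(list(cx = pos[1], cy = pos[2], a = r, b = r,
                                 theta = 0), c(sz, sz))
    H[px] <- spec$hema_level * 1.2
  }
  for (q in seq_len(spec$n_junk)) {
    aj <- runif(1, 5, 9); bj <- runif(1, 2, 4)
    pos <- place_clear(aj)
    if (is.null(pos)) next
    px <- rasterize_ellipse(list(cx = pos[1], cy = pos[2], a = aj, b = bj,
                                 theta = runif(1, 0, pi)), c(sz, sz))
    H[px] <- spec$hema_level * 0.55
  }

  # eosin field: band-limited stroma texture, sparse fibers, reduced inside
  # nuclei
  etex <- smooth_noise(sz, sz, sigma = 10)
  E <- spec$eosin_level * (0.85 + 0.25 * pmin(pmax(etex, -2), 2))
  nfib <- max(0L, as.integer(sz / 80))
  for (q in seq_len(nfib)) {
    x0 <- runif(1, 1, sz); y0 <- runif(1, 1, sz)
    ang <- runif(1, 0, 2 * pi); len <- runif(1, 40, 150)
    tseq <- seq(0, len, by = 0.5)
    xs <- round(x0 + tseq * cos(ang)); ys <- round(y0 + tseq * sin(ang))
    keep <- xs >= 2 & xs <= sz - 1 & ys >= 2 & ys <= sz - 1
    xs <- xs[keep]; ys <- ys[keep]
    if (length(xs) == 0L) next
    for (dr in -1:1) for (dc in -1:1)
      E[cbind(ys + dr, xs + dc)] <- E[cbind(ys + dr, xs + dc)] +
        0.25 * spec$eosin_level
  }
  E[nuc_px] <- E[nuc_px] * 0.35

  tile <- render_he_tile(H, E, vectors)
  nuclei <- data.frame(id = seq_len(n), cx = P$cx, cy = P$cy,
                       a = P$a, b = P$b, theta = P$theta,
                       area_px = as.numeric(tabulate(lab[lab > 0L], nbins = n)))
  structure(list(tile = tile, labels = lab, nuclei = nuclei, spec = spec),
            class = "synth_tile")
}

#' @export
print.synth_tile <- function(x, ...) {
  cat(sprintf("synthetic H&E tile %dx%d (%s), %d nuclei, seed %d\n",
              x$spec$size, x$spec$size, x$spec$preset,
              nrow(x$nuclei), x$spec$seed))
  invisible(x)
}
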