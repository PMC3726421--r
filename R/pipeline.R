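# Full pipeline: unmix -> per-scale preprocessing -> two marker-controlled
# watersheds per scale -> feature rejection + ellipse standardization ->
# cross-scale merging.

#' Pipeline configuration
#'
#' Collects every tunable parameter with the published defaults: scale set
#' `{10, ..., 18}` (disk radii, matching the expected range of nucleus minor
#' semi-axes at 0.25 um/px), FRST radius sets `{n, ..., 2n}` with marker
#' basin depth `h = 0.4`, feature ranges `s` in (0.875, 1), `l` in (20, 255),
#' `d` in \[0, 0.08\], band width 3 px, and merge overlap threshold 0.2.
#'
#' @param stain a [stain_vectors()] object.
#' @param scales integer vector of preprocessing scales (strictly
#'   increasing).
#' @param h extended-minima depth for FRST markers, on the normalized
#'   symmetry map.
#' @param frst_alpha,frst_kappa,frst_gauss_factor,frst_grad_floor internal
#'   FRST constants (radial strictness, vote clamp, Gaussian width factor,
#'   gradient floor fraction).
#' @param marker_types which marker types to run (`"frst"`, `"minima"`).
#' @param feature_ranges list with elements `s`, `l`, `d`, each `c(lo, hi)`.
#' @param band_width boundary-saliency band width in pixels.
#' @param overlap_th merge overlap threshold.
#' @return object of class `nucseg_config`.
#' @export
nucseg_config <- function(stain = stain_vectors(),
                          scales = 10:18,
                          h = 0.4,
                          frst_alpha = 2, frst_kappa = 9.9,
                          frst_gauss_factor = 0.25, frst_grad_floor = 0.05,
                          marker_types = c("frst", "minima"),
                          feature_ranges = list(s = c(0.875, 1),
                                                l = c(20, 255),
                                                d = c(0, 0.08)),
                          band_width = 3,
                          overlap_th = 0.2) {
  scales <- as.integer(scales)
  if (length(scales) == 0L || any(scales < 2L) ||
      (length(scales) > 1L && any(diff(scales) <= 0L)))
    stopf("scales must be strictly increasing integers >= 2")
  marker_types <- match.arg(marker_types, c("frst", "minima"), several.ok = TRUE)
  structure(list(stain = stain, scales = scales, h = h,
                 frst_alpha = frst_alpha, frst_kappa = frst_kappa,
                 frst_gauss_factor = frst_gauss_factor,
                 frst_grad_floor = frst_grad_floor,
                 marker_types = marker_types,
                 feature_ranges = feature_ranges,
                 band_width = band_width,
                 overlap_th = overlap_th),
            class = "nucseg_config")
}

#' @export
print.nucseg_config <- function(x, ...) {
  cat("nucseg pipeline configuration\n")
  cat("  scales:        ", paste(x$scales, collapse = " "), "\n")
  cat("  marker types:  ", paste(x$marker_types, collapse = ", "), "\n")
  cat("  FRST: h =", x$h, " alpha =", x$frst_alpha, " kappa =", x$frst_kappa,
      " gauss =", x$frst_gauss_factor, "r  grad floor =", x$frst_grad_floor, "\n")
  cat(sprintf("  features: s in (%.3f, %g), l in (%g, %g), d in [%g, %g], band %g px\n",
              x$feature_ranges$s[1], x$feature_ranges$s[2],
              x$feature_ranges$l[1], x$feature_ranges$l[2],
              x$feature_ranges$d[1], x$feature_ranges$d[2], x$band_width))
  cat("  overlap threshold:", x$overlap_th, "\n")
  invisible(x)
}

empty_candidates <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
             theta = numeric(0), scale = integer(0),
             marker_type = character(0), fitness = numeric(0),
             s = numeric(0), l = numeric(0), d = numeric(0),
             area = numeric(0), stringsAsFactors = FALSE)
}

# feature-filter the regions of one watershed run and standardize the
# survivors as ellipses
collect_candidates <- function(lab, pre, n, marker_type, cfg) {
  k <- max(lab)
  if (k == 0L) return(empty_candidates())
  idx_all <- which(lab > 0L)
  regions <- split(idx_all, lab[idx_all])
  amin <- n^2 * pi
  amax <- 4 * n^2 * pi
  out <- empty_candidates()
  for (reg in regions) {
    area <- length(reg)
    if (area < amin || area > amax) next       # cheap gate first
    ft <- compute_region_features(reg, pre, cfg$band_width)
    keep <- filter_candidates(
      data.frame(s = ft$s, l = ft$l, d = ft$d, area = ft$area),
      n, cfg$feature_ranges)
    if (!keep) next
    e <- tryCatch(fit_ellipse(reg, nrow(pre), fitness = ft$s),
                  error = function(err) NULL)
    if (is.null(e)) next
    out <- rbind(out, data.frame(cx = e$cx, cy = e$cy, a = e$a, b = e$b,
                                 theta = e$theta, scale = n,
                                 marker_type = marker_type, fitness = ft$s,
                                 s = ft$s, l = ft$l, d = ft$d, area = area,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Segment the nuclei in an H&E tile
#'
#' Runs the full multiscale, multimarker pipeline: hematoxylin unmixing,
#' morphological simplification at every scale in the configuration, a
#' FRST-marker and a regional-minima-marker watershed at each scale,
#' rule-based rejection with ellipse standardization, and greedy cross-scale
#' merging. With the default 9 scales and both marker types, 18 watershed
#' segmentations feed the candidate pool. The pipeline is fully
#' deterministic.
#'
#' @param tile h x w x 3 RGB array in \[0, 255\], or an object with a
#'   `$tile` element (e.g. a [generate_tile()] result).
#' @param cfg a [nucseg_config()].
#' @param verbose print per-scale candidate counts.
#' @return object of class `nucseg_result`: list with `ellipses` (accepted
#'   regions: `cx, cy, a, b, theta, scale, marker_type, fitness` plus their
#'   features), `pixsets` (rasterized accepted ellipses), `label_map`
#'   (earlier-accepted regions win shared pixels), `n_candidates` and
#'   `per_scale` counts.
#' @export
segment_tile <- function(tile, cfg = nucseg_config(), verbose = FALSE) {
  if (is.list(tile) && !is.null(tile$tile)) tile <- tile$tile
  assert_tile(tile)
  hema <- hematoxylin_image(tile, cfg$stain)
  dims <- dim(hema)
  pool <- empty_candidates()
  per_scale <- data.frame(scale = integer(0), marker_type = character(0),
                          markers = integer(0), candidates = integer(0))
  for (n in cfg$scales) {
    pre <- tryCatch(preprocess_at_scale(hema, n), error = function(e)
      stopf("preprocessing failed at scale %d: %s", n, conditionMessage(e)))
    for (mt in cfg$marker_types) {
      fg <- if (mt == "frst") {
        sym <- frst_orientation_only(pre, frst_radius_set(n),
                                     alpha = cfg$frst_alpha,
                                     kappa = cfg$frst_kappa,
                                     gauss_factor = cfg$frst_gauss_factor,
                                     grad_floor = cfg$frst_grad_floor)
        extract_frst_markers(sym, cfg$h)
      } else {
        extract_minima_markers(pre, n)
      }
      cand <- empty_candidates()
      if (max(fg) > 0L) {
        ms <- tryCatch(
          marker_set(fg, build_background_marker(fg, n), mt, n),
          error = function(e)
            stopf("marker construction failed at scale %d (%s markers): %s",
                  n, mt, conditionMessage(e)))
        lab <- watershed_with_markers(pre, ms)
        cand <- collect_candidates(lab, pre, n, mt, cfg)
        pool <- rbind(pool, cand)
      }
      per_scale <- rbind(per_scale,
                         data.frame(scale = n, marker_type = mt,
                                    markers = max(fg), candidates = nrow(cand)))
      if (verbose)
        message(sprintf("scale %2d %-6s: %4d markers, %3d candidates",
                        n, mt, max(fg), nrow(cand)))
    }
  }
  merged <- merge_candidates(pool, dims, th = cfg$overlap_th)
  acc <- merged$accepted
  rownames(acc) <- NULL
  structure(list(ellipses = acc,
                 pixsets = merged$pixsets,
                 label_map = label_map_from_pixsets(merged$pixsets, dims),
                 n_candidates = merged$n_candidates,
                 per_scale = per_scale,
                 config = cfg),
            class = "nucseg_result")
}

#' @export
print.nucseg_result <- function(x, ...) {
  cat(sprintf("nucseg segmentation: %d accepted nuclei (from %d candidates)\n",
              nrow(x$ellipses), x$n_candidates))
  if (nrow(x$ellipses) > 0)
    cat(sprintf("  mean ellipse area: %.0f px; scales used: %s\n",
                mean(pi * x$ellipses$a * x$ellipses$b),
                paste(sort(unique(x$ellipses$scale)), collapse = " ")))
  invisible(x)
}
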