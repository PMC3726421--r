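# Cross-scale merging: overlap measure, adjacency, greedy fitness selection.

#' Overlap measure between two pixel sets
#'
#' `|Xi intersect Xj| / min(|Xi|, |Xj|)`: 1 when one region is contained in
#' the other, 0 when they are disjoint.
#'
#' @param xi,xj integer vectors of linear pixel indices (non-empty).
#' @return value in \[0, 1\].
#' @export
overlap_measure <- function(xi, xj) {
  if (length(xi) == 0L || length(xj) == 0L)
    stopf("overlap measure is undefined for empty regions")
  n_intersect(xi, xj) / min(length(xi), length(xj))
}

#' Build the candidate adjacency matrix
#'
#' Two candidates are adjacent iff their overlap measure strictly exceeds
#' `th`; pairs at or below the threshold count as merely "touching" and may
#' both survive merging. Pairs whose bounding circles cannot intersect are
#' skipped.
#'
#' @param pixsets list of pixel index vectors (rasterized ellipses).
#' @param centers optional 2-column matrix of (x, y) centers and `radii`
#'   vector of bounding radii, used to prune distant pairs.
#' @param radii see `centers`.
#' @param th overlap threshold (default 0.2).
#' @return symmetric logical adjacency matrix with `FALSE` diagonal.
#' @export
build_adjacency <- function(pixsets, centers = NULL, radii = NULL, th = 0.2) {
  k <- length(pixsets)
  A <- matrix(FALSE, k, k)
  if (k < 2L) return(A)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!is.null(centers)) {
        d2 <- (centers[i, 1] - centers[j, 1])^2 + (centers[i, 2] - centers[j, 2])^2
        if (d2 > (radii[i] + radii[j])^2) next
      }
      if (overlap_measure(pixsets[[i]], pixsets[[j]]) > th)
        A[i, j] <- A[j, i] <- TRUE
    }
  }
  A
}

#' Resolve concurrent candidates by greedy fitness selection
#'
#' Repeatedly accepts the unresolved candidate with the maximal fitness and
#' rejects every candidate adjacent to it, until all candidates are accepted
#' or rejected. No two accepted candidates are adjacent. Fitness ties are
#' broken deterministically by larger area, then lower scale, then FRST
#' before regional-minima provenance, then input order.
#'
#' @param fitness numeric fitness per candidate (the region solidity).
#' @param adjacency logical adjacency matrix from [build_adjacency()].
#' @param area,scale,marker_type optional tie-break keys, recycled defaults
#'   when missing.
#' @return integer vector of accepted candidate indices, in acceptance order.
#' @export
resolve_overlaps <- function(fitness, adjacency,
                             area = rep(0, length(fitness)),
                             scale = rep(0L, length(fitness)),
                             marker_type = rep("frst", length(fitness))) {
  k <- length(fitness)
  if (k == 0L) return(integer(0))
  mrank <- ifelse(marker_type == "frst", 0L, 1L)
  ord <- order(-fitness, -area, scale, mrank, seq_len(k))
  state <- integer(k)  # 0 unresolved, 1 accepted, -1 rejected
  accepted <- integer(0)
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    accepted <- c(accepted, i)
    nb <- which(adjacency[i, ] & state == 0L)
    state[nb] <- -1L
  }
  accepted
}

#' Merge candidate ellipses from all scales and marker types
#'
#' Rasterizes every candidate ellipse, builds the overlap adjacency at
#' threshold `th`, and runs the greedy fitness resolution. Returns the
#' accepted subset (rows of `candidates`, in acceptance order) together
#' with their pixel sets.
#'
#' @param candidates data frame with columns `cx`, `cy`, `a`, `b`, `theta`,
#'   `scale`, `marker_type`, `fitness`.
#' @param dims image dimensions `c(nrow, ncol)`.
#' @param th overlap threshold (default 0.2).
#' @return list with `accepted` (data frame), `pixsets` (list, parallel to
#'   the accepted rows) and `n_candidates`.
#' @export
merge_candidates <- function(candidates, dims, th = 0.2) {
  k <- nrow(candidates)
  if (k == 0L)
    return(list(accepted = candidates, pixsets = list(), n_candidates = 0L))
  pixsets <- lapply(seq_len(k), function(i)
    rasterize_ellipse(candidates[i, ], dims))
  ok <- lengths(pixsets) > 0L
  candidates <- candidates[ok, , drop = FALSE]
  pixsets <- pixsets[ok]
  k <- nrow(candidates)
  A <- build_adjacency(pixsets,
                       centers = cbind(candidates$cx, candidates$cy),
                       radii = candidates$a, th = th)
  acc <- resolve_overlaps(candidates$fitness, A,
                          area = lengths(pixsets),
                          scale = candidates$scale,
                          marker_type = candidates$marker_type)
  list(accepted = candidates[acc, , drop = FALSE],
       pixsets = pixsets[acc],
       n_candidates = k)
}

# paint accepted ellipses into a label map; earlier-accepted regions win on
# the (<= th) overlap pixels that two accepted ellipses may share
label_map_from_pixsets <- function(pixsets, dims, ids = seq_along(pixsets)) {
  lab <- matrix(0L, dims[1L], dims[2L])
  for (i in seq_along(pixsets)) {
    px <- pixsets[[i]]
    px <- px[lab[px] == 0L]
    lab[px] <- ids[i]
  }
  lab
}
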