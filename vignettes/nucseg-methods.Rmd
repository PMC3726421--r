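---
title: "Multiscale marker-controlled watershed segmentation of H&E nuclei: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale marker-controlled watershed segmentation of H&E nuclei: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucseg)
```

## The problem and the model

Epithelial nuclei in hematoxylin and eosin (H&E) stained breast-cancer
sections are the unit of analysis for nuclear morphometry (mean nuclear
area, pleomorphism-related features). At a 40x scan resolution of about
0.25 µm/pixel, their minor semi-axes span roughly 10–18 pixels. `nucseg`
segments them with a multiscale, multimarker marker-controlled watershed:

1. **Stain unmixing.** Bright-field image formation follows the
   Lambert–Beer law, `I_c = I0_c · 10^(−OD_c)` per detection channel
   `c ∈ {R,G,B}`, with optical density linear in stain concentrations:
   `OD = M · (c_H, c_E, c_res)`. Given the 3×3 matrix `M` of per-channel
   absorption coefficients (unit-norm columns; defaults are the standard
   published H&E coefficients, residual completed by a normalized cross
   product), concentrations are recovered by solving the linear system per
   pixel and clipping negatives. The hematoxylin single-stain image is
   re-rendered through the forward model and collapsed to grayscale with
   BT.601 luminance weights, giving an image in which nuclei are dark. The
   concentration map itself is also available
   (`hematoxylin_image(..., concentration_map = TRUE)`).
2. **Morphological simplification at a scale `n`.** Opening by
   reconstruction then closing by reconstruction, both with a discrete
   Euclidean disk of radius `n`, followed by a plain closing with a disk of
   radius `round(n/2)`. Reconstruction filters remove bright/dark
   structures in which the disk does not fit while leaving surviving
   contours exactly in place; the final closing removes thin protrusions.
   A consequence used deliberately by the multiscale design: a nucleus
   whose minor diameter is below the disk diameter is erased entirely at
   that scale, so each scale "sees" only nuclei of its own size class.
3. **Markers.** Two independent marker types per scale. *FRST markers*:
   the orientation-only fast radial symmetry transform is computed for
   radii `{n, …, 2n}`; unit votes are cast one radius inward along each
   sufficiently strong Sobel gradient (dark-center polarity), clamped at
   `κ`, raised to the radial-strictness power `α`, Gaussian-smoothed
   proportionally to the radius, and averaged over radii. The response is
   normalized to [0, 1] and inverted so nucleus centers are minima;
   markers are its extended regional minima at depth `h = 0.4`.
   *Regional-minima markers*: the regional minima of the preprocessed
   image, excluding border-touching plateaus and plateaus larger than the
   maximal nucleus area `4n²π`. The background marker assumes each
   foreground marker marks a nucleus of the maximal radius `2n`: markers
   are dilated by `2n` and the morphological skeleton (Guo–Hall thinning)
   of the complement is used, guaranteeing a thin, disjoint background
   seed.
4. **Watershed.** The Sobel gradient magnitude of the preprocessed image
   is the segmentation function; regional minima are imposed at the marker
   locations by the standard reconstruction-by-erosion construction, and
   Meyer flooding with watershed lines grows exactly one region per
   marker. The background-grown region is discarded.
5. **Rejection and standardization.** Each region is scored on the image
   it was segmented from: solidity `s` (pixel count over the pixel count
   of the rasterized convex hull, the standard region-properties
   convention), boundary saliency `l` (median intensity in a 3-px band
   outside minus a 3-px band inside; gray levels), mass displacement `d`
   (distance between centroid and inverse-intensity-weighted centroid,
   weights `256 − I`, normalized by the minor axis length of the moment
   ellipse), and pixel area. A region is kept iff
   `s ∈ (0.875, 1)`, `l ∈ (20, 255)`, `d ∈ [0, 0.08]` and
   `n²π ≤ area ≤ 4n²π`, each bound at exactly that open/closed sense.
   Survivors are standardized as moment ellipses (same second central
   moments, with the 1/12 pixel-extent term so a disk of radius `r` fits
   semi-axes `r`), carrying their solidity as a fitness value.
6. **Cross-scale merging.** All candidates from 9 scales × 2 marker types
   enter one pool. For rasterized ellipse pairs the overlap measure is
   `OV(X_i, X_j) = |X_i ∩ X_j| / min(|X_i|, |X_j|)`; pairs with
   `OV > 0.2` (strictly) are adjacent, pairs at or below 0.2 merely
   "touching". Greedy resolution repeatedly accepts the unresolved
   candidate with maximal fitness and rejects its adjacent candidates, so
   no two accepted regions overlap above threshold.

Evaluation follows a Dice-based protocol: a ground-truth nucleus is a true
positive iff some automatic region reaches Dice ≥ 0.2 with it (the best
match per nucleus, without exclusivity — one automatic region may serve
two nuclei); sensitivity is TP/(TP+FN) and the median Dice is reported
over matches, which is robust to the left-skewed Dice distribution.
Object-level positive predictive value is the fraction of automatic
regions whose best Dice against any ground-truth nucleus reaches 0.2 — a
surrogate for expert labeling of sampled regions, usable on synthetic
data; it counts junk/distractor segmentations against the method exactly
as a rater would. Mean nuclear area (MNA) is the mean of accepted ellipse
areas `πab`; a linear correction `true ≈ slope·auto + intercept`, fitted
by least squares on paired per-image MNA values, removes the systematic
underestimation caused by small spurious segmentations and
under-segmented large nuclei.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| scale set | 10…18 | px | expected nucleus minor semi-axes at 0.25 µm/px |
| FRST radii | n…2n | px | nucleus radii reconstructed well at scale `n` |
| `h` | 0.4 | normalized response | basin depth for FRST markers |
| `α`, `κ` | 2, 9.9 | – | radial strictness, vote saturation |
| FRST Gaussian | 0.25·r | px | see below |
| gradient floor | 5% of max | – | suppresses votes from flat texture |
| `s` range | (0.875, 1) | – | nuclei are rarely concave |
| `l` range | (20, 255) | gray levels | dark object on brighter surround |
| `d` range | [0, 0.08] | minor-axis fractions | symmetric interior intensity |
| area bounds | n²π…4n²π | px | plausibility at the segmenting scale |
| band width | 3 | px | "tight band" for the saliency medians |
| `T_h` | 0.2 | – | small overlap of touching nuclei allowed |
| Dice cutoff | 0.2 | – | excludes matches by mere touching |

**FRST smoothing width.** The per-radius Gaussian width is `0.25·r`. With
`0.5·r` the vote peaks of two touching nuclei whose centers are about
`2n` apart fuse into a single basin, so clusters receive one marker and
are segmented as a peanut-shaped region that the solidity filter then
rejects; `0.25·r` keeps the two basins separate, which is precisely the
situation FRST markers exist to handle. The constant is exposed in the
configuration (`frst_gauss_factor`).

**Solidity convention.** Solidity is pixel count divided by the number of
pixel centers inside the convex hull taken over the pixel edge midpoints
(the ±0.5 axis offsets) — the convention of standard region-properties
implementations, against which the package is cross-checked in its tests.
It is strictly below 1 for any curved boundary (a discrete disk of radius
12 measures ≈ 0.948), which keeps the open upper bound of the `s` range
from discarding ideal elliptical regions, while blocky artifacts can
still reach 1 and be rejected.

## Numerical and algorithmic choices

- **Connectivity** is 8 for all foreground operations (minima, components,
  watershed flooding), applied consistently; complements are analysed with
  4-connectivity where duality matters (tests).
- **Border handling**: morphological operators pad by replication, so the
  image border introduces no artificial minima; regional-minima markers
  additionally exclude border-touching plateaus.
- **Erosion/dilation by a disk** is decomposed into per-column-offset van
  Herk/Gil-Werman running-min filters (O(1) per pixel per offset); binary
  dilation for the background map uses the exact Euclidean distance
  transform. Grayscale reconstruction uses the hybrid raster-scan + FIFO
  algorithm.
- **h-minima** follows the reconstruction definition literally:
  reconstruction by erosion of `img + h` over `img`. On a constant image
  this lifts the plateau by `h` — the minima structure, which is all the
  marker extraction consumes, is unchanged.
- **Gaussian smoothing** in the FRST uses an exact separable kernel for
  σ ≤ 2 and a three-pass box cascade for larger σ (O(1) per pixel
  independent of σ); at the σ values involved the difference is far below
  the vote quantization.
- **Watershed determinism**: flooding ties are broken by insertion order
  (FIFO among equal priorities); ridge pixels get label 0. Identical
  inputs give bit-identical outputs, and candidates are pooled in a
  canonical order (scale, then marker type) before merging.
- **Merge tie-breaks**: equal fitness is resolved by larger area, then
  lower scale, then FRST before minima provenance, then input order — a
  total order, so merging is deterministic.
- **Label maps** rasterize accepted ellipses in acceptance order; on the
  (≤ 0.2 overlap) pixels two accepted ellipses may share, the
  earlier-accepted region wins.
- **Degenerate inputs**: a constant symmetry map yields no markers; an
  image with no markers yields an empty (not failed) segmentation; a
  marker set whose dilation covers the frame raises an error naming the
  scale; ellipse fitting refuses < 5 pixels and collinear sets (detected
  on the uncorrected second moments).

## The synthetic tile generator

`generate_tile()` renders H&E-like tiles through the same Lambert–Beer
forward model the unmixing inverts: elliptical nuclei (minor semi-axes
10–18 px, aspect 1–1.5) with high hematoxylin concentration and
multiplicative band-limited chromatin noise; an eosin-textured stroma
with sparse fiber strokes; optional lymphocyte-like distractors (dark
disks of radius 4–7 px) and faint elongated junk particles. Difficulty
presets fix the study conditions: *easy* (well-separated, chromatin noise
0.05, no distractors), *medium* (30% of nuclei placed touching a
neighbor, noise 0.12, 6 lymphocytes + 8 junk particles), *hard* (50%
clustered, noise 0.15, a marginalized-chromatin rim — brighter interior,
darker rim — and more distractors). Clustered nuclei are placed at 98% of
the touching distance along a random direction, so pairs overlap
marginally; contested pixels go to the nearer nucleus in the normalized
ellipse metric, keeping the label mask a partition. All randomness flows
from the single seed through a private RNG stream (the caller's RNG state
is untouched), and a fixed seed reproduces the tile byte for byte.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: stain variability between laboratories and
scanners, out-of-focus and compression artifacts, tubule architecture,
dense lymphocytic infiltration, necrosis, and nuclei cut by the tile
border (nuclei are placed fully inside the frame). Results on these tiles
characterize the implementation, not clinical performance.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the operator oracles on ≥ 200 random instances
up to 28×28, the watershed contract on 60 fuzzed marker sets, and the
end-to-end pipeline on 10 easy + 10 medium tiles of 512×512 px with ~40
nuclei each, 10 bimodal-size tiles for the multiscale-vs-single-scale
comparison, and 20 small tiles for the MNA correction. The acceptance
script reruns the pipeline on 4 tiles per condition plus one 1000×1000
tile for a runtime figure; these sizes were chosen so a complete
desk-scale replication stays in the minutes range on one CPU while every
quantity is still estimated from hundreds of nuclei.

## Known limitations

- Elliptical standardization discards contour detail; shape features
  beyond axes/orientation would need a contour-refinement step.
- The rule-based filter is deliberately simple (no learned classifier);
  its ranges were designed for 0.25 µm/px — other magnifications need a
  rescaled scale set (e.g. 5–9 px at 20x).
- Lymphocytes are mostly invisible to the default scale set by design;
  the package contains no dedicated lymphocyte detector.
- Whole-slide processing (tiling, stitching, tissue sampling) is out of
  scope; the unit of work is a tile that fits in memory.

## A minimal session

```{r example, eval = FALSE}
tile <- generate_tile(synth_spec("medium", seed = 11))
res <- segment_tile(tile$tile)
res
match_and_score(tile$labels, res)
mean_nuclear_area(res)
```
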