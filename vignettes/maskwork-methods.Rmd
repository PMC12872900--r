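---
title: "maskwork: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maskwork: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maskwork)
```

This vignette is the package's own account of the statistics and algorithms
it implements, the conventions and parameter defaults it commits to, and
what its synthetic test bed does and does not demonstrate about real data.

## Setting

Promptable segmentation models can pre-label instance-segmentation
datasets: an automatic mask generator (AMG) proposes masks over a whole
image from an internal point grid, or a point/box prompt requests one mask
at a location. A human then accepts, refines or discards the drafts.
`maskwork` provides the measurement layer for such pipelines — mask quality
scores, annotation-oriented matching, prompt construction, hyperparameter
search, cross-image annotation transfer, and inter-annotator consensus —
behind two minimal backend contracts (a mask-proposal closure and a
promptable-segmenter closure), so any model, or the built-in mocks, can be
plugged in.

## Conventions

* A binary mask is a logical matrix; `mask[r, c]` covers pixel
  `(x = c − 1, y = r − 1)`, 0-based, x = column, y = row, origin top-left.
  All modules inherit this raster convention.
* Geometry (homographies, prompts, warps) lives in *pixel-center*
  coordinates: the continuous point `(x, y)` is the center of pixel
  `(x, y)`.
* Polygon rasterization is the one corner-origin operation: vertices are
  continuous coordinates on the pixel-corner lattice, and a pixel is filled
  iff its center `(x + 0.5, y + 0.5)` is inside the closed polygon under
  the even-odd rule, boundary ties counting as inside. This center rule is
  deterministic and is verified against an exhaustive point-in-polygon
  oracle; with vertices on integer corners it fills exactly the geometric
  area (a `w × h` rectangle fills `w·h` pixels).
* Label maps are interchanged as single-channel 16-bit PNGs (value 0 =
  background, `k` = instance `k`); they cannot express overlap, so
  overlapping sets must use COCO-style JSON with uncompressed column-major
  RLE, which round-trips losslessly. The package writes 16-bit PNGs with
  its own minimal encoder (null-filter scanlines, zlib stream, compiled
  CRC32) and reads them through the `png` package.

## Scores

**IoU** is `|A ∩ B| / |A ∪ B|`; two empty masks give 0 with a `degenerate`
attribute instead of `NaN`, so batch pipelines never propagate missing
values. **Generalized Dice** uses inverse-square class weights
`w_l = 1/(Σ_i y_il)²` over object and background; a class absent from the
ground truth would get infinite weight and is dropped from numerator and
denominator — equivalent to weight zero, keeping the score finite and equal
to 1 for perfect predictions. **F_β** is
`(1 + β²)PR/(β²P + R)`, defined as 0 on a vanishing denominator; β = 2
(the default throughout) weights recall β² = 4 times as much as precision,
encoding that discarding a surplus proposal costs an annotator less than
drawing a missed object. All ratios are computed in double precision;
closed-form test cases are asserted at absolute tolerance 1e-9.

## Matching semantics

Matching is existential and per ground-truth instance: a ground truth is a
TP iff at least one proposal has IoU **strictly greater** than the
threshold (default 0.8) with it; a proposal is an FP iff it exceeds the
threshold with no ground truth, contributing at most one FP however many
ground truths it misses. One proposal may certify several (e.g. stacked,
occluded) ground truths, so TP can exceed the number of distinct proposals;
duplicate proposals never change counts. The comparison operator is
exposed (`strict = FALSE` gives ≥ semantics) so the boundary behavior is
testable. A bounding-box prefilter skips pixel counting for pairs whose
boxes do not intersect; results are provably identical to the naive double
loop, and the tests verify that equivalence on random scenes.

## Geometric-median prompts

The canonical interior prompt of a mask is the geometric median of its
foreground pixel centers — the point minimizing the summed Euclidean
distance to them — computed by Weiszfeld iteration with the Vardi–Zhang
correction for iterates landing on data points (stop when the iterate
moves < 1e-6 px or after 1000 iterations; sub-pixel accuracy suffices
because the result is snapped to a pixel). The continuous optimum is then
snapped *onto the mask* by taking the foreground pixel minimizing the same
objective, with row-major tie-breaking: for ring-like masks the
unconstrained median falls in the hole and would prompt background, and
for L-shaped masks the pixel nearest the continuous optimum is not always
the best on-mask pixel. On masks above 2048 px the candidate set is
restricted to the 256 pixels nearest the continuous optimum — the argmin
cannot snap far from it — keeping the operation linear in practice.

## Grid search

A grid specification maps each of the seven AMG hyperparameters
(`points_per_side`, `points_per_batch`, `pred_iou_thresh`,
`stability_score_thresh`, `stability_score_offset`, `crop_n_layers`,
`crop_n_points_downscale_factor`) to a candidate list; the default spans
three values for six of them with the batch size fixed, i.e. 729
configurations. The harness treats the values as opaque — their semantics
live in the backend — and expands the grid lexicographically in canonical
field order, which also breaks ranking ties deterministically. Each
configuration is scored as the arithmetic mean over images of the F₂
obtained by matching the backend's proposals to the ground truth. Backend
errors are caught per configuration, recorded with the offending
configuration, and excluded from the ranking; an all-failing grid returns
an empty ranking plus the full failure list rather than raising. A single
global seed is threaded to the backend as a per-configuration derived
sub-seed (all derived seeds stay below 2³¹).

Per-image F₂ on an image without ground-truth instances is excluded by
precondition rather than defined: the evaluation images in this setting
always contain instances, and any silent convention would bias means.

## Homography estimation and transfer

No OpenCV binding is available to R, so the registration pipeline is
implemented in the package on top of EBImage convolution primitives,
keeping the classical stage structure of keypoint panorama stitching:

1. **Detection** — Harris corner response (Sobel gradients, Gaussian
   window σ = 1.5 px, k = 0.04), 8-neighbor non-max suppression, top
   `max_keypoints = 1500` corners, quadratic sub-pixel refinement, 16 px
   border margin.
2. **Description** — orientation from the intensity centroid of a 7 px
   disc (as in rotation-aware binary descriptors), then a 12×12 patch
   sampled bilinearly on a grid rotated to that orientation (spacing
   1.4 px), mean-subtracted and unit-normalized.
3. **Matching** — cosine distances on unit descriptors, Lowe ratio test at
   0.75, mutual cross-check.
4. **Estimation** — RANSAC (1000 iterations, 3 px reprojection threshold,
   internal seed 42 so estimation is deterministic) over normalized-DLT
   4-point fits, followed by two least-squares refits on the consensus
   set. A full projective model is fitted; the mild-projective synthetic
   warps stay well inside its capacity.

Each stage fails with an error naming the stage (detection / matching /
estimation), so a featureless image is distinguishable from degenerate
geometry. On noise-free synthetic pairs (512×512) the estimate reproduces
the true warp to well under 1 px corner reprojection error.

Transfer projects each source instance's tight bounding box through the
homography: the box envelope's four corners are mapped, their axis-aligned
integer cover is clipped to the target frame, and boxes keeping less than
`min_inside = 25 %` of their envelope area inside are dropped (the
fraction is a parameter; clipping versus dropping at the frame edge is a
policy choice, not a reconstruction of any reference tool). Surviving
boxes are prompted to the segmenter on the target image; empty or failing
segmentations are recorded as drops with reasons. Scoring matches the
transferred set against the target image's reference only — instances are
deliberately not tracked across images.

## Consensus statistics

The annotation frequency `f_a,px = N_assigned / N_rounds` counts, per
pixel, the rounds in which the pixel belonged to at least one mask.
Within-round multiplicity counts once — that binarization is what makes
the frequency a proper proportion in [0, 1] — while raw multiplicity
remains available through `overlap_map()`. The display filter retains
pixels assigned more than once (`n_assigned ≥ 2`). The over-/
under-segmentation summary pairs each reference instance with each round's
best-IoU counterpart (a declared pairing rule; qualitative color analyses
do not fix one): counterpart pixels spilling beyond the reference count as
*under-segmentation*, reference pixels the counterpart misses count as
*over-segmentation*, averaged over rounds with a positive-IoU counterpart.

## The synthetic test bed

`generate_scene()` places non-overlapping (by default) textured ellipses —
semi-axes 8–16 px at the default 256×256 frame — on a low-frequency
background with fine speckle, recording exact per-instance masks; every
output is a pure function of `(params, seed)`. The speckle is there for
the corner detector, the shading for non-trivial Dice values.
`warp_scene()` renders the overlapping second view under an exact
homography (bilinear for the image, nearest-neighbor for labels to keep
masks binary — the source of ≤ 1 px boundary jitter under rotation, which
is why rotation tests assert IoU ≥ 0.99 rather than identity).
`mock_proposal_backend()` perturbs each ground-truth mask to a requested
IoU by eroding or dilating in order of signed boundary distance with
seeded jitter, choosing the retained pixel count so the achieved IoU is
exact to within one pixel in the area (subset: IoU = |M|/|gt|; superset:
|gt|/|M|); requested bands unreachable on tiny instances are logged and
the instance emitted unperturbed. Spurious proposals are blobs placed
disjoint from the ground truth; the spurious rate is an exact per-image
count so closed-form precision predictions hold. `oracle_segmenter()`
answers prompts directly from ground truth.

What passing tests on these scenes demonstrate: the bookkeeping, formulas
and geometry are correct, deterministic, and agree with independent
brute-force oracles. What they do not demonstrate: performance on real
imagery — real kernels are denser, lighting varies, instance boundaries
are ambiguous, real AMG proposal errors are not morphological
perturbations, and real overlapping views violate the planar-homography
assumption away from shallow scenes. Conclusions about a real model still
require plugging real backends into the same harnesses.

## Problem sizes

The shipped test suite and the acceptance script size their simulations
for a laptop-class single core: oracle-equivalence properties run 100–200
random instances per operation on 10–24 px frames; the point-prompt
protocol uses 10 images × 10 instances at 128×128; registration and
transfer checks use one 512×512 pair with 25 instances (plus 256×256 pairs
in unit tests); the failure-tolerance search runs the full 729-point grid
against a cheap ground-truth-echo backend, and planted-optimum recovery
uses a 6-point grid with the quality-controlled mock. These sizes are the
package's chosen defaults for its own verification, scaled so the entire
suite completes in well under a minute.

## Known limitations

* Label PNGs silently quantize nothing but cannot express overlap; the
  writer refuses overlapping sets instead of flattening them.
* Compressed (string-encoded) COCO RLE is not parsed; uncompressed integer
  counts are emitted and accepted.
* The registration pipeline assumes textured, mostly planar, mostly
  rotation-aligned views (orientation normalization handles moderate
  in-plane rotation); it has no scale pyramid, so large scale changes
  between views will fail at the matching stage.
* `f_a,px` uses the binary per-round reading of assignment; an
  alternative multiplicity-counting reading would exceed 1 on overlapping
  annotations and is intentionally not used.
* Video-style mask propagation is represented only through the segmenter
  contract plus transfer scoring; propagation internals are out of scope.
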