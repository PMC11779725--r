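---
title: "Stomatal morphometry from epidermal micrographs: models and methods"
author: "stomataMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomatal morphometry from epidermal micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomataMorph)
```

## The problem

Stomata — the pore complexes of the leaf epidermis, each built from a pair
of guard cells with their pore and the flanking subsidiary cells — control
gas exchange and transpiration. In maize, stomatal density, size and shape
shift with leaf position and reproductive stage, and hybrids differ from
their parental inbred lines in ways that bear on photosynthetic efficiency
and water use. Quantifying this requires measuring thousands of stomata
from electron micrographs of the abaxial (lower) epidermis: detecting and
counting complexes in low-magnification fields of view, segmenting the
complex and its guard-cell-and-pore (GCP) region at high magnification,
and reducing each complex to a standard set of traits.

`stomataMorph` implements that pipeline as composable, tested pieces:

1. a **synthetic epidermis generator** with exact analytic ground truth,
2. calibrated **image/annotation I/O** (PNG/TIFF, YOLO boxes, labelme-style
   polygons, 0/255 mask PNGs, trait CSVs),
3. a pluggable **detector** and **segmenter** contract, each with a
   deterministic classical reference implementation,
4. **mask fusion** and **connectivity-based instance extraction**,
5. **morphometry**: the 11 standard traits,
6. **evaluation metrics** (precision, recall, AP50, GIoU loss, Dice, IoU,
   reliability regression), and
7. a **statistical layer** (correlation matrices, one-way ANOVA with a
   compact letter display, z-score PCA, heterosis rates).

Learned detectors/segmenters (YOLO-family, U-Net-family) are deliberately
*not* trained here: trained weights are not reproducible from published
summaries, so the package defines the contract they must honour
(image in, scored boxes / mask pair out) and ships classical reference
implementations that satisfy the contract exactly on synthetic imagery.
Any learned model can be dropped in where a `DetectionResult` or
`MaskPair` is consumed.

## Physical calibration

Micrographs are square frames at fixed magnification presets: a 350x field
covers 767 um x 767 um (suited to counting; stomata appear as dark files
on a bright background) and a 900x field covers 298 um x 298 um (suited
to morphology). At the native 1024 px frame this gives 0.749 and 0.291
um/px respectively; the scale is always derived as field length / pixel
count, so resizing an image (bilinear for intensities, nearest-neighbour
for masks) rescales um/px while conserving the physical field — stomatal
density is therefore resolution-invariant by construction.

## The synthetic epidermis model

The generator (`generateScene()`) is first-class, tested code, not a test
fixture. It emulates the geometry of the maize abaxial epidermis:

* **Placement.** Stomata sit in parallel longitudinal files (the rows a
  grass leaf actually shows). Files are laid across the field at
  `rowSpacingUm` (default 78 um) with a small lateral jitter; positions
  along each file come from a jittered slot grid whose pitch exceeds the
  largest possible stoma, and every candidate is re-checked against all
  accepted bounding boxes with a minimum inter-complex gap of 8 um
  (neighbouring complexes are separated by pavement cells, never
  abutting), so ground-truth boxes are disjoint and the rendered
  complexes are well-separated 8-connected components. The requested
  count is `round(targetDensity x field area)`; if the geometry cannot
  hold that many, the maximum placeable number is used and a warning
  records the shortfall.
* **Shape.** Each complex is an ellipse with length and width drawn from
  truncated normal distributions (defaults 95 +/- 5 um by 55 +/- 2 um,
  within the realistic maize ranges of roughly 85-105 um by 52-59 um),
  its long axis along the file with a uniform orientation jitter
  (default +/- 6 degrees). The GCP region is a concentric ellipse scaled
  by `sqrt(f)` on both axes so that its area fraction is exactly the drawn
  `f` (default 0.50 +/- 0.02). An ellipse is chosen because it gives
  closed-form truth for every trait; real guard-cell pairs are
  dumbbell-shaped, which the model does not attempt.
* **Rendering.** Background, subsidiary and GCP pixels take three gray
  levels (defaults 180 / 120 / 50) that must be pairwise >= 20 levels
  apart — this *is* the contract the reference segmenter relies on.
  Additive Gaussian noise (default sd 4; the stress tests use 8) is
  clipped to [0, 255].
* **Determinism.** One private RNG stream per scene, seeded from
  `params@seed` and never touching the caller's RNG state: identical
  parameters give bit-identical scenes.

What passing tests on this generator do **not** show: robustness to real
SEM texture, charging artifacts, focus gradients, overlapping or touching
stomata, or non-elliptical cell outlines. The generator validates the
*measurement* machinery (given a correct segmentation, traits are
recovered to known tolerance), not any particular learned model.

Default densities (80 per mm^2, within the observed 70-95 range) and the
GCP fraction near 0.5 reflect published cultivar-level summaries for
maize; row spacing and orientation jitter are plausibility choices, since
spatial statistics of stomatal files are rarely reported.

## Traits and numerical choices

For each extracted instance (scale `s` um/px):

| Trait | Definition | Notes |
|---|---|---|
| SD | count / field area (per mm^2) | field-of-view level |
| SA | pixel count x `s`^2 | exact in pixel units |
| SP | sub-pixel outer contour length x `s` | see below |
| SL, SW | long/short side of the minimum-area rotated rectangle | rotating calipers over the pixel-corner hull |
| GCPA | GCP pixel count x `s`^2 | GCP pixels intersected with the instance first |
| SCA | SA - GCPA | never negative |
| SR | 4 pi SA / SP^2 | 1 for a circle |
| SE | sqrt(1 - lambda2/lambda1) of the second central moment matrix | pixels as unit squares (+1/12 diagonal) |
| PGCPA, PSCA | GCPA/SA, SCA/SA | sum to 1 exactly |

Numerical decisions that matter:

* **Perimeter.** Counting boundary pixels biases SR low by 10-20%, and a
  raw marching-squares polygon of a binary mask overestimates a disk's
  circumference by ~6% (SR ~ 0.89 for a perfect disk). SP is therefore
  the marching-squares 0.5-level contour (outer contour only, largest
  enclosed area) refined by three passes of 1-2-1 vertex smoothing; a
  rasterized disk then measures SR in [0.99, 1.00] for radii from 10 px
  up, and the published cultivar-mean consistency check
  (4 pi x 4140.05 / 288.45^2 = 0.63 at two decimals) holds.
* **SL/SW from the rotated rectangle**, not the axis-aligned box: stomatal
  files are oriented, and axis-aligned extents would inflate SW for any
  tilted stoma.
* **Eccentricity from moments**, because it generalizes
  sqrt(1 - (SW/SL)^2) to arbitrary blobs and is rotation-stable.
* **8-connectivity** for instance extraction (standard for blob
  labelling); the underlying 4-connected labeller is augmented by a
  diagonal-adjacency union-find merge, fuzz-tested against a flood-fill
  oracle.
* **Border policy.** Instances touching the frame edge have truncated
  geometry; by default (`drop_for_traits`) they are excluded from
  size/shape tables but still flagged, reported and counted for density.
  Whether field studies exclude them is usually unstated; both policies
  are exposed.
* **Mean of ratios.** Per-stoma traits are computed first and then
  averaged, matching the per-individual trait definitions; consistency
  checks that recompute a ratio from *averaged* numerator and denominator
  are therefore approximate (Jensen's inequality) and are treated as such.

## Evaluation metrics

Detection: greedy one-to-one matching in descending confidence at
IoU >= 0.5, precision = TP/(TP+FP), recall = TP/(TP+FN) (the universal
definitions), and AP50 as the area under the all-point-interpolated
precision-recall curve (a 101-point variant sits behind a flag; the two
differ negligibly). The GIoU loss
`1 - (IoU - |Z \ (X u Y)| / |Z|)` uses the smallest enclosing axis-aligned
box Z. Segmentation: Dice and IoU with the identity
IoU = Dice/(2 - Dice); a pair of empty masks scores 1 (perfect agreement
on absence) with a warning, never silently. Reliability assessment fits
manual values on automated outputs by OLS and reports the squared Pearson
correlation together with the raw-pair RMSE
`sqrt(sum((x_i - y_i)^2) / n)` — note the RMSE is computed on the raw
automated/manual differences, not on fit residuals.

Undefined ratios (no predictions, no truths, zero-variance traits) always
surface as errors or NA-with-reason, never as a silent 0.

## Statistical layer

* **Correlations**: pairwise-complete Pearson r with two-sided p from the
  t distribution on n-2 df; p-values are reported raw (no multiplicity
  correction is applied, and none is implied).
* **ANOVA letters**: one-way ANOVA, Tukey HSD at alpha = 0.05 (the
  standard companion for letter displays; the choice of post-hoc test is
  otherwise open), and an insert-and-absorb compact letter display with
  groups ordered by descending mean, first letter "a". The display is
  property-tested: two groups share a letter iff their Tukey p >= alpha,
  and the letter partition matches the `multcomp` reference
  implementation.
* **PCA**: traits are z-scored with the sample SD (n-1), the correlation
  matrix is eigendecomposed, contributions are eigenvalues / number of
  traits (summing to 100%), and the sign of each component is fixed by
  making its largest-magnitude loading positive, so results are
  deterministic.
* **Heterosis**: for an F1 with parents P1, P2, the mid-parent rate
  `(F1 - MP)/MP` with `MP = (P1+P2)/2`, plus over-high-parent and
  over-low-parent rates. Published "super-parental" figures rarely state
  which convention they use, so all three are always emitted; on the
  bundled cultivar means the stomatal-density mid-parent rate is -0.096,
  matching the published ~ -0.09 in sign and closely in size, while size
  traits are positive under every convention.

## Worked pipeline

```{r pipeline, eval = FALSE}
params <- sceneParams(targetDensity = 80, noiseSd = 8, seed = 7)
scene <- generateScene(params)              # 47 stomata in 0.588 mm^2

det <- referenceDetect(scene@image)
stomatalDensity(detectionCount(det), scene@image)   # 79.89 / mm^2

seg  <- referenceSegment(scene@image)
inst <- labelStomata(fuseMasks(seg), seg@gcpMask)
tab  <- stomaTraitTable(inst, umPerPx(scene))
aggregateTraits(tab, by = "cultivar")
```

## Problem sizes and tolerances

The shipped tests and the acceptance script run the full pipeline on one
1024 px / 767 um scene per condition (47 stomata at density 80 per mm^2,
noise sd 8), a noise-free 46-stoma scene for exact detection checks, a
400 px scene for structural tests, 500-record simulated trait tables for
the statistical layer, and about 1000 fuzzed mask pairs (<= 64 px) for the
metric identities — sizes at which every guarantee is tight yet a full
run stays in the order of a minute. Documented tolerances: SA within 2%
of analytic truth, SL/SW within 3%, SE and PGCPA within 0.02, density
within 2%; metric identities hold to 1e-12 and oracle equivalences to
1e-9 or exactly.

## Known limitations

* The reference detector/segmenter assume the generator's intensity-band
  contract; on real micrographs they are a baseline only, and the learned
  models they stand in for must be supplied by the user.
* Touching or overlapping stomata are not split (the generator never
  produces them; a watershed step would be needed for crowded tissue).
* Only planar, abaxial morphology is modelled: no aperture state, no
  adaxial surfaces, no 3-D depth.
* The elliptical GCP model makes PGCPA exact by construction; real
  dumbbell guard-cell geometry would add shape-dependent error that the
  synthetic tests cannot see.
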