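---
title: "Methods: mitochondrial TEM morphometry and segmentation evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial TEM morphometry and segmentation evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## Scope and model

`mitomorph` analyzes mitochondria in 2-D TEM sections of glioma tissue.
Its unit of observation is the *instance*: one mitochondrion's pixel mask
(or polygon) inside one imaged tumor cell, at a known physical calibration
in microns per pixel. On top of instances it computes five morphometric
indices (per-cell density and area ratio; per-instance area, perimeter,
circularity), cristae occupancy, a three-type cristae-health label, the
LGG/HGG grade grouping, group-wise statistics, and — when a second set of
instances is a model's prediction — the evaluation statistics used to
decide whether that model is good enough to replace manual tracing:
macro-averaged Precision/Recall/F1 after score- and IoU-thresholded
matching, plus signed perimeter and area error rates over matched pairs.

Segmentation itself (network training/inference) is out of scope: the
package evaluates and analyzes instances from any source.

## Conventions that matter

**Coordinates and rasterization.** Pixels are 1-based `(x, y)`, origin
top-left, y down. Polygons use the COCO convention (continuous coordinates,
origin at the image's top-left corner), and a pixel belongs to a polygon
iff its *center* `(x − 0.5, y − 0.5)` is inside (even-odd rule). Because
reading and writing use the same center-sampling rule, COCO round trips
are pixel-exact, and a 10 × 10 axis-aligned square rasterizes to exactly
100 pixels.

**Perimeter of raster masks.** The choice of perimeter estimator moves
circularity by up to ten points and is the least standardized convention in
this field, so it is worth being explicit. We measure the length of the
traced outer boundary (Moore tracing of boundary-pixel centers, one 1-2-1
vertex-smoothing round) **plus π**. The additive π is not a fudge factor:
boundary-pixel centers sit half a pixel inside the true mask boundary, and
offsetting a closed curve outward by `d` adds `d · (total turning) = 2πd`
for a simply connected region, so `d = 0.5` px contributes exactly π. We
rejected three alternatives after measuring them on digitized discs and
squares: the raw marching-squares polyline (runs ~5.6 % long on smooth
boundaries; digitized discs plateau at circularity ≈ 0.90), and the Kulpa
and Vossepoel–Smeulders chain-code weightings (accurate for large smooth
shapes but pushing small discs and squares to circularity 1.08–1.12). The
offset-corrected smoothed trace keeps digitized discs within ~1 % of
`2πr` down to `r ≈ 6` px and never exceeds circularity 1.05 at area
≥ 100 px, which is the contract the tests enforce. Analytic polygons use
shoelace area and summed edge lengths and satisfy `circularity ≤ 1`
exactly. Holes in masks are treated as annotation noise: area counts the
mask's pixels as given and the perimeter always follows the outer contour.
A single-pixel instance is degenerate and is measured as its half-pixel
offset disc (perimeter π) with a warning.

**Matching cardinality.** A TP rule of the form "score ≥ 0.5 and any
ground-truth IoU ≥ 0.5" does not by itself forbid two predictions claiming
one ground truth; counting FNs as "the remaining ground truths" presupposes
a one-to-one matching. We therefore match greedily in descending IoU (ties:
higher score, then lower prediction id). With non-overlapping ground truth
— guaranteed for label images — a prediction can have IoU ≥ 0.5 with at
most one ground truth, so greedy matching provably equals the exhaustive
optimum (maximum matched pairs, then maximum total IoU); the test suite
verifies this against a brute-force assignment oracle on 500 random
configurations.

**Macro averaging.** The Precision/Recall/F1 formulas place `1/N` outside
a per-image ratio, so every metric is computed per image and averaged over
images; images where a ratio is undefined (zero denominator) are excluded
from that metric's mean and reported in `n_images_used`. The same applies
to the error rates (mean over an image's TP pairs, then mean over images
with at least one TP). A per-instance (micro) pooling is deliberately not
the primary output.

**The area-error-rate typo.** The published display equation for the area
error rate reads `(A_pred − A_pred)/A_pred`, which is identically zero — an
evident typo. The package implements the perimeter-analogous
`(A_pred − A_gt)/A_gt`. Signed rates can cancel across pairs, so the mean
absolute companion is always reported next to the signed value.

**Three-type classification.** Human typing of cristae health is visual.
The package's proxy is a fixed decision table on cristae occupancy and the
OMM flag: occupancy < 0.10 → Type 3; occupancy ≥ 0.50 with intact (or
unknown) OMM → Type 1; everything else → Type 2; with occupancy missing,
the OMM flag alone distinguishes Type 2 (intact) from Type 3 (ruptured).
Boundary values classify upward (toward the healthier type) — arbitrary
but fixed. The thresholds are an operationalization for synthetic
pipelines, not clinically validated criteria, and human-assigned labels in
the annotations always override the proxy. The rule is monotone in
occupancy for a fixed OMM state.

**Statistics.** Kruskal–Wallis or ordinary (equal-variance) one-way ANOVA
across grades; Mann–Whitney U (mid-rank ties, normal approximation) or the
unpaired two-tailed Student t test for LGG vs HGG. Raw p-values are the
default, matching the source panels; a Holm column is available
(`adjust = TRUE` in `compare_groups_table()`). Whether the mitochondrion,
the cell or the image is the statistical unit is a genuine modelling
choice (per-mitochondrion tests pseudoreplicate within cells), so
`compare_groups(unit =)` exposes all three and defaults to the
mitochondrion, which is how the source counts its n. Radar summaries
min–max rescale group means per metric (two groups: smaller mean → 0,
larger → 1; a constant metric → 0.5 with a note), a display normalization
chosen here because none is stated in the source material.

## The synthetic generator: what it emulates, and what a green test means

`generate_ground_truth()` builds wobbly elliptical cells, each packed with
a non-overlapping population of mitochondrion blobs (ellipses with
low-order radial Fourier noise — star-shaped, never self-intersecting),
each carrying a cristae sub-mask realized as an interior stripe pattern
thresholded at the drawn occupancy fraction, an OMM flag, and (in the
default type-driven mode) a cristae-type label. Everything is a pure
function of `(spec, seed)`; the written annotation JSON is byte-identical
across runs, and infeasible packings fail loudly naming the image.

The default per-grade profiles encode *directions only* — toward high
grade: more mitochondria per cell, smaller areas (lognormal median 0.40 →
0.20 µm²), rounder shapes (mean circularity 0.62 → 0.84), and a richer
Type-1 fraction (0.20 → 0.55), with LGG/HGG magnitudes invented at a size
a morphometrist would call plausible for tumor tissue. The source material
reports these contrasts qualitatively and prints no distribution
parameters, so the profiles must not be read as estimates of the clinical
data — and a green group-comparison test establishes that the *pipeline
detects a contrast of this size in the stated direction*, not that the
clinical effect has any particular magnitude. Likewise the generator omits
real-TEM nuisances: no texture, no staining gradients, no touching or
overlapping organelles, no annotation error on the ground-truth side.

`GradeProfile` carries both a type mixture and marginal occupancy/OMM
parameters because the source links them only qualitatively; the generator
therefore supports two sampling modes. Type-driven (default): draw the
type from the mixture, then occupancy and OMM from fixed type-conditional
tables (dense cristae and near-certainly intact OMM for Type 1, nearly
vanished cristae and mostly ruptured OMM for Type 3). Occupancy-driven
(`type_mixture = NULL`): draw occupancy from the profile's beta and the
OMM flag from `p_omm_intact`, and leave typing to the proxy.

`generate_predictions()` perturbs ground truth with controllable,
*recoverable* errors: drops (→ FN), spurious blobs placed at IoU < 0.5
against every ground truth (→ FP), an expected-IoU target met by solving
for a translation per instance, and signed perimeter/area biases applied
in polygon space — area via centroid scaling by `sqrt(1 + area_bias)`,
perimeter via a high-frequency radial ripple (or radial smoothing for
shortening) solved to the target length. The ripple changes area only at
second order (< 0.2 % at the tested settings), which is why a +10 %
perimeter bias and a −15 % area bias can be injected jointly and recovered
by the error rates to within ±0.02 at ≥ 100 TP pairs. Strong negative
perimeter biases are the one direction the mechanism cannot always reach
(a shape cannot be smoother than convex); the tuner then warns and returns
its smoothest shape.

## Numerical choices and degenerate inputs

* IoU of two empty masks is an error, not 0; empty *images* are valid
  (zero instances) everywhere.
* Score filtering applies only to predictions; a prediction without a
  score is retained, and ground truth never carries scores. Score exactly
  0.5 is retained; IoU exactly 0.5 is a TP.
* Boundary-straddling instances are assigned to the cell containing the
  majority of their pixels; instances overlapping no cell stay unassigned
  and are excluded from per-cell summaries.
* Cristae masks must be subsets of their mitochondrion mask (enforced at
  construction); absent cristae annotation yields an absent occupancy, not
  zero.
* The built-in TIFF codec covers exactly the exchange subset it writes —
  uncompressed single-channel 8/16-bit, either byte order on read — and
  was cross-validated against an independent implementation; compressed
  or multi-sample TIFF is rejected loudly. PNG label images are read at
  any depth but written 8-bit (≤ 255 labels) by the available encoder.
* Default synthetic images are 512 px at 0.02 µm/px. At 256 px the default
  high-grade profiles exceed ~40 % cell fill and rejection packing
  rightly fails; use ≥ 384 px with the defaults.

## Known limitations

2-D sections only (no tomography); no intensity-based features; no
mitochondrial network topology; no learned cristae classifier — the
three-type proxy is threshold-based; prediction perturbation needs
polygonal ground truth for shape biases; and the evaluation implements the
bespoke four-statistic protocol, not COCO AP curves.
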