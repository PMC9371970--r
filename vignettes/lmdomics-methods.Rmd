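---
title: "LMDomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LMDomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LMDomics)
```

LMDomics implements the computational backbone of image-guided single-cell
proteomics: cells or nuclei are segmented in scanned microscopy images,
classified into morphological or marker-defined phenotypes, physically
excised by laser microdissection (LMD) class by class into 384-well plates,
profiled by low-input mass spectrometry, and the resulting per-class
proteomes are painted back onto the image. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-fixture tests do and do not establish.

## Segmentation and its evaluation

The deep-learning segmenters used in production imaging pipelines are
deliberately out of scope here; any external tool's label masks can be
imported (`readLabelMaskTIFF()`) and dropped into the same evaluation and
planning steps. What the package ships is a classical baseline,
`baselineSegment()`: Gaussian blur, a background-robust detection threshold
(median + 5 MAD of the blurred image), a distance-transform watershed to
split touching candidates, then a *local* Otsu cut per watershed region.
The local cut is the load-bearing choice: nuclei in one field commonly span
a several-fold brightness range, and a single global threshold either
swallows dim nuclei or dilates bright ones through their blur halo.
A recovery pass re-thresholds removed chunks whose distance-map depth is at
least 2 px, which rescues a dim nucleus that shared a candidate region with
a much brighter neighbour. Objects below `min_area_um2` (default 10 µm²)
are discarded as speckle.

Accuracy follows the standard instance-segmentation protocol: predicted and
ground-truth objects are matched one-to-one, a pair being eligible when its
intersection-over-union exceeds the threshold $t$ (strictly; default
$t = 0.7$), and

$$\mathrm{precision}(t) = \frac{TP}{TP+FP},\quad
  \mathrm{recall}(t) = \frac{TP}{TP+FN},\quad
  F_1(t) = \frac{2\,\mathrm{precision}\cdot\mathrm{recall}}
                {\mathrm{precision}+\mathrm{recall}}.$$

Matching maximizes the number of matches (augmenting-path maximum
cardinality), with ties broken by descending IoU then ascending labels. At
$t \ge 0.5$ the matching is forced anyway — an object can overlap at more
than 0.5 IoU with at most one partner — so the maximum-cardinality rule
only matters for exploratory low thresholds. Degenerate 0/0 ratios are
defined as 1 (and $F_1 = 1$ only when both masks are empty): an empty
prediction against an empty truth is vacuously perfect. Batch evaluation
reports the mean F1 and its across-image standard error, the convention
used when comparing segmentation methods across fields of view.

## Morphological phenotyping

`extractFeatures()` computes, per object: area (pixel count × px²),
perimeter, solidity (area / convex hull area), form factor
($4\pi A/P^2$; 1 for a perfect disk), per-channel total and mean
intensity, and the number of neighbouring centroids within a configurable
radius (default 50 µm). The perimeter is measured on the sub-pixel
marching-squares boundary, lightly smoothed with a 3-point circular moving
average. The smoothing is not cosmetic: the raw marching-squares polygon of
a digitized disk is a chamfered staircase whose perimeter overestimates
$2\pi r$ by about 7%, which would push the form factor of a perfect disk
down to ~0.87; after smoothing a disk of radius 20 px scores
$\ge 0.95$. Discretization can still push solidity or form factor slightly
above 1 for small objects; values up to 1.05 should be read as 1.

Classification is either supervised gating on a marker channel
(`gateByMarker()`: class 1 strictly above the cutoff, class 2 otherwise) or
the unsupervised *phenotype finder* (`phenotypeFinder()`): features are
z-scored — per-feature standardization puts area (hundreds of µm²) and
solidity (≈1) on the same footing — and clustered by k-means with 25
restarts under a fixed seed, so results are reproducible. The number of
classes `k` is a user decision; `silhouetteScan()` reports mean silhouette
widths as guidance only. Classes are renumbered by descending frequency,
giving stable labels across runs. `radarSummary()` reports per-class means
of the standardized features, whose frequency-weighted grand mean is 0 by
construction.

## LMD planning

`maskToContours()` polygonizes each object's outer boundary (holes are
discarded — the laser cuts outer boundaries only) with counter-clockwise
orientation under the pixel-centre convention: pixel (row r, col c),
1-based, has its centre at ((c − ½)·px, (r − ½)·px) µm, origin top-left,
x rightward, y downward. `offsetContour()` buffers the polygon outward
(Minkowski sum with a disk, round joins, via the Clipper polygon engine) so
the cut clears the membrane; the default offset is 1 µm, configurable
per run, and the arc discretization tolerance is 0.5% of the offset so
buffered areas are accurate to well under 1%.

`orderCuts()` minimizes stage travel over contour centroids for the open
path from a start point: exact Held–Karp dynamic programming up to 10
contours, nearest-neighbour construction plus 2-opt refinement beyond,
deterministic tie-breaking toward lower contour indices. Centroids, not
laser entry points, define the travel metric; entry-point optimization is a
refinement left out of scope.

`registerCoordinates()` fits the six-parameter affine map from scan to
stage coordinates by least squares on at least three non-collinear fiducial
pairs. Affine rather than similarity: it absorbs slight axis anisotropy
between microscopes. The RMS per-point residual is retained on the object
so degraded fiducials are visible; exactly collinear fiducials are rejected
as a degenerate fit.

Two pieces of throughput arithmetic are exposed directly:
`theoreticalAccuracyUm(m)` = 10/m µm (≈70 nm at ×150), and
`estimateCellCount(area, thickness, volume)` = area × thickness / volume
with the 2,000 µm³ average mammalian cell volume as default — 80,000 to
160,000 µm² of a 2.5 µm section is 100–200 cells.

`assignWells()` routes contours to 384-well plates either one class per
well or by chunking a fixed number of objects per well, and reports
per-well object counts and summed areas so samples can be matched by
object count or by area. Plans are exchanged as a documented, bit-exact
contour XML dialect (root `ImageData`, three `Calibration_i` points,
`Shape_i` elements with `CapID` well ids and `X_j`/`Y_j` vertices as
integer nanometres, rounded half-up); the reader accepts the same dialect,
so write → read is the identity at nm precision. Vendor schemas are
proprietary, so this dialect is the package's own, and adapters for vendor
formats are expected to map onto it.

## Proteomics statistics

`filterMatrix()` removes decoy/contaminant/site-only rows, treats zeros as
missing (non-detections are reported as 0 by common quantification tools)
and keeps proteins with at most 30% missing values — the boundary is
inclusive. `imputeDownshift()` replaces each missing cell with a draw from
$\mathcal N(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)$, where $\mu_j$ and
$\sigma_j$ are the observed moments of the cell's sample column: a
narrowed, left-shifted distribution mimicking below-detection-limit
intensities. Per-column imputation is the default (each sample has its own
depth); a `scope = "global"` switch uses whole-matrix moments instead.

The two-group statistic is the s0-moderated t,
$d = (\bar a - \bar b)/(s_0 + \mathrm{se})$ with the pooled-variance
standard error (n−1 denominators throughout) and $s_0 = 0.1$ by default;
$s_0 = 0$ recovers Student's t exactly, which the tests assert. Multi-group
comparisons use the classical one-way F (with a $10^{-12}$ variance floor
for the all-identical degenerate case); for two groups $F = t^2$.

Significance uses a permutation-based FDR. For a symmetric cutoff $c$ on
the absolute statistic,
$$\widehat{\mathrm{FDR}}(c) =
  \frac{\overline{\#\{|d^{perm}| > c\}}}{\max(1, \#\{|d^{obs}| > c\})},$$
where the numerator averages over group-label permutations (all distinct
assignments are enumerated when there are at most `n_perm` of them — 70
for a 4 vs 4 design — otherwise `n_perm` random draws). A protein's
q-value is the smallest estimated FDR over the cutoffs that call it, and
proteins with q ≤ 0.05 are flagged by default. One numerical choice
deserves emphasis: the per-cutoff permutation counts are aggregated by
their **mean**, with the median available as an option. The median looks
more robust but is unstable exactly where it matters — at extreme cutoffs
the per-permutation count is a small integer, and a median of 0 certifies
an estimated FDR of exactly 0 for the top-ranked protein whenever half the
permutations happen to produce no exceedance, which on a complete null
occurs often enough to break error control. The mean keeps every
permutation's contribution (the identity relabelling is always part of the
enumerated set, flooring the estimate at 2/70 for a balanced 4 vs 4) and
is calibrated in the package's null simulations while detecting planted
2-unit effects with essentially full sensitivity.

`fisherEnrichment()` tests each annotation term's 2×2 table (in-term/not ×
significant/not) one-sided for enrichment; the p-value is the upper
hypergeometric tail, Benjamini–Hochberg adjusted across terms within one
run (cross-run correction is the caller's concern), with the sample odds
ratio and a hypergeometric z-score reported alongside.

## Spatial re-integration

`readGeometryXML()` parses per-class geometry exports (the package's
contour dialect, or a minimal generic polygon XML) into one cell table,
compounding ids as class_index so duplicate ids across class files stay
distinct. `classPathwayScores()` computes, per annotation term, the
**median** level over the term's member proteins per class, then z-scores
across classes. Scores are per class, painted onto every cell of that
class: the proteomes are measured per class, not per cell, and per-cell
scores would misrepresent the data. Whether the colour scale should be
normalized across classes or against the whole slide is genuinely open;
both are exposed (`normalize = "classes"` default, `"global"` option).
`renderTissueHeatmap()` draws cell centroids on a symmetric diverging
scale centred at 0, y axis reversed to match image coordinates, with
missing-score classes in a neutral colour and reported via a message.

## Synthetic fixtures: what they are and what they show

`makeImageFixture()` renders non-overlapping rotated ellipses with
multiplicative log-normal texture (s.d. 0.1), additive Gaussian read noise,
and a six-class morphology panel: three primary classes at frequencies
0.33/0.30/0.28 and three rare ones at 0.03 each, spanning 25–120 µm² with
distinct eccentricity ranges and staining intensities — the frequency
regime of heterogeneous cultured nuclei populations. Placement is rejection
sampling with at most 100 attempts per object and a 3 px clearance margin;
partial placement is reported, not an error, since tests control density.
`makeProteomeFixture()` draws log2 intensities Gaussian within group around
protein baselines (mean 25, s.d. 2), plants a fixed log2 fold change
between groups 1 and 2 in a known protein subset, and censors values with
logistic dropout in the latent intensity — the
missing-not-at-random regime for which downshifted imputation is the
appropriate remedy. `makePhenotypeFixture()` places Gaussian classes at the
vertices of a regular simplex so every pair of classes is equally
separated in within-class s.d. units.

These generators define the package's study conditions: fields of 50
nuclei on 512×512 px at 0.5 µm/px for segmentation, 3,000 objects with
6-s.d. class separation for phenotype recovery, 1,000 proteins in 4 vs 4
designs for the statistics. Ellipses exercise the area / perimeter /
solidity / form-factor axes but are deliberately not photorealistic: no
overlapping or touching nuclei, no uneven illumination, no out-of-focus
blur, no chromatin substructure. A perfect score on the fixtures therefore
demonstrates correctness of the algorithms under their stated assumptions,
not performance on real tissue, where segmentation quality is dominated by
factors the baseline segmenter does not model — that is precisely why the
segmenter is a pluggable contract.

## Degenerate inputs and tie-breaking, collected

* Empty masks are legal everywhere: empty object lists, empty contour
  lists, empty cut plans; precision/recall default to 1 on 0/0.
* IoU of two empty pixel sets is rejected as undefined.
* Constant features abort `phenotypeFinder()` with a message; `k = n` is
  served by the degenerate one-object-per-class assignment.
* Zero-offset buffering returns the input contour unchanged; negative
  offsets are errors.
* Collinear fiducials are a degenerate affine fit and are rejected.
* Columns with fewer than two observed values cannot be imputed and raise
  an error.
* XML vertex coordinates round half-up to integer nanometres; all
  geometry round-trips exactly at that precision.

## Problem sizes

The shipped tests run the full pipeline at the study conditions above:
10-image segmentation batches, 3,000-object clustering, 20-seed null
simulations of the 1,000 × 8 permutation FDR, 100-polygon buffering and
100-plan XML round trips, and exhaustive matching/path oracles up to 6
objects per mask side and 8 contours per path. These sizes were chosen so
the whole suite documents the method at desk scale; all scale linearly or
quadratically upward in the obvious way.
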