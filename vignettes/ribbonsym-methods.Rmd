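---
title: "Scoring local parallelism in line drawings and tracing its BOLD signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring local parallelism in line drawings and tracing its BOLD signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonsym)
```

## The problem

Local parallelism — two contours keeping a roughly constant separation, as
along the sides of a road, a tree trunk, or a door frame — is a perceptual
grouping cue. `ribbonsym` provides an image-computable measure of it for
line drawings (a local *ribbon symmetry* score per contour pixel), tools to
manipulate it (splitting a drawing into most- and least-parallel halves
with exactly equal contour-pixel counts), and the two fMRI analyses that
consume the measure: multivoxel scene-category decoding from block-design
data, and model-based deconvolution of event-related data with the
per-image parallelism rating as a parametric regressor, followed by
gamma-mode peak-latency comparisons between regions of interest (ROIs).

Because the original stimulus set and BOLD recordings are not packaged,
every analysis is exercised on synthetic data whose ground truth is known
by construction. The generators are first-class, tested code.

## The ribbon-symmetry score

1. **Distance transform.** For a binary raster of the drawing we compute
   the exact Euclidean distance of every pixel to the nearest contour
   pixel (`distance_transform()`, two-pass lower-envelope algorithm in
   C++, verified against a brute-force oracle).
2. **Medial axis.** The medial axis of the white space is the locus where
   the gradient of the distance function is multi-valued. On a grid we
   detect it by the *average outward flux* of the normalized distance
   gradient through each pixel's 8-neighborhood: skeleton pixels are sinks
   of that field. Pixels with flux below `flux_threshold` (default
   `-0.25`) form the axis. The canvas border is not a contour; since only
   contour pixels seed the distance transform, no border skeleton arises
   and no discard step is needed.
3. **Radius function and windowed change counting.** Each axis pixel
   carries its radius `R` (its distance-map value). Axis pixels are traced
   into simple branches split at junctions (`trace_branches()`). For each
   axis point, a window of `W` points (default 11) centered on it within
   its branch counts `n`, the number of consecutive radius differences
   exceeding `epsilon` (default 0.5 px). The score is
   `sigma = 1 - n / (W_eff - 1)`, with `W_eff` the realized (truncated)
   window length. Constant radius means locally parallel contours and
   `sigma = 1`; a radius that changes at every step gives `sigma = 0`.
4. **Projection to contours.** Each axis point passes `sigma` to the
   contour pixels it flows to on both sides: the nearest contour pixel
   per side (following the distance gradient) plus that pixel's contour
   neighbors within `R + 0.5` of the axis point — the discrete stand-in
   for the multi-valued contact set, since the distance transform records
   only one nearest pixel even at ties. A contour pixel is flanked by a
   skeleton on either side and keeps the **maximum** of the received
   scores. Pixels reached by no axis point inherit the score of the
   nearest assigned pixel of the same contour (ties take the larger
   score), or 0 if their contour received nothing.
5. **Image rating.** `average_parallelism()` is the unweighted mean score
   over all contour pixels; it is the per-image parametric value used in
   the event-related analysis.

### Parameter choices

| parameter | default | why |
|---|---|---|
| `W` | 11 axis points | the window must be long enough to see a trend yet local; the source method leaves the value to its own methods reference, so it is configuration here |
| `epsilon` | 0.5 px | absorbs the quantization of `R` on the pixel grid, so exactly parallel digital lines score 1 |
| `flux_threshold` | -0.25 | a flat distance field has flux about 0; the midline between two contours has flux about -0.6; -0.25 separates the two robustly |
| score map | `1 - n/(W_eff - 1)` | the source describes only a monotone decreasing map of the change count; linear is the simplest order-preserving choice bounded in [0, 1] |

Windows truncate at branch ends (no padding or wrap: there is no basis for
extrapolating the radius). Sub-pixel geometry is not attempted; the score
is a window count and insensitive to sub-pixel refinement.

### Known discretization effects

* At odd inter-contour separations the flux ridge is two pixels thick; the
  axis mask is thinned (Zhang-Suen) to unit width before tracing,
  otherwise branch tracing and window counts are corrupted.
* Junction pixels are appended to one incident branch so that branches
  partition the axis and arc indices stay consecutive.
* For **axis-aligned** parallel digital lines the end ridge (the locus
  equidistant from the two line endpoints) is perpendicular to the
  midline, forms its own branch, and every contour pixel of the pair
  scores exactly 1. For **diagonal** pairs the end ridge continues
  *collinearly* into the midline branch, so windows near the transition
  count radius changes and a few end pixels score slightly below 1. The
  drawing generator therefore uses axis-aligned pairs as its
  exactly-parallel exemplars. In drawings with several shapes, interacting
  end ridges can still leave an isolated end pixel below 1 (order 1 in
  10^3 pixels); invariant tests on mixed drawings assert monotonicity
  rather than exact equality to 1.
* Translation and 90-degree-rotation invariance of the average score is
  exact in the continuum but approximate on the grid, because
  outer-skeleton branches are clipped differently by the canvas;
  the tests allow a 0.05 tolerance on mixed drawings.

## Splitting into half-images

Contour pixels are rank ordered by score; the top half becomes the
most-parallel half-image and the bottom half the least-parallel one, so
both contain an equal number of contour pixels (the description of the
original stimuli ranks *contours* in one place and *pixels* in another;
only pixel-level ranking can guarantee the stated exactly-equal pixel
counts, so that is what is implemented). Ties are broken by a seeded
uniform shuffle, making the split deterministic under a fixed seed; for an
odd pixel count the extra pixel goes to the most-parallel half.

## Experimental designs

* **Block design** (`build_block_design()`): 9 runs; each run has 18
  blocks, one per scene category (6) x image condition (intact / most /
  least); a block shows 8 images for 800 ms with 200 ms gaps (8 s); 10 s
  fixation precedes the first block and follows every block. A run is
  334 s = 167 volumes at TR = 2 s; a participant yields 1503 volumes.
* **Event design** (`build_event_design()`): one image per 10 s trial
  (1 s presentation, 9 s fixation), seeded order, parametric values
  (parallelism, luminance, contrast) attached to events.
* **Tent design matrix** (`build_tent_design_matrix()`): 7 tent (FIR)
  basis functions with apexes at 0, 2, ..., 12 s after onset (one beta
  per TR covering onset to 12 s; apexes at 2-14 s would not yield a beta
  *at* each acquisition time and were rejected). Tents are causal (zero
  before onset). Parametric amplitudes are mean-centered per regressor
  and an unmodulated event regressor is appended, so stimulus occurrence
  and its parametric modulation are decorrelated; this standard practice
  is a choice here, as the source does not state it. Per-run quadratic
  polynomial drift columns complete the matrix (the deconvolution tool
  used by the source includes polynomial baselines by default).

## Synthetic data: what it emulates, what it does not

`generate_drawing()` places ribbon pairs (congruent polylines at constant
normal separation, optionally jittered), wedges (line pairs at an opening
angle, the canonical non-parallel shape: the radius grows by about
`tan(angle/2)` per unit of axis length), and random open curves in
disjoint grid cells of the canvas. Shape counts per drawing are sampled
around the base specification so a stimulus set has natural variability;
every drawing keeps at least one non-parallel shape so the most/least
split is never degenerate. What it does **not** emulate: contour density
and length distributions of artist-traced scenes, junctions between
objects, closed regions, or any category-specific structure — a green
test says the pipeline is correct, not that synthetic drawings look like
scenes.

`simulate_block_bold()` builds voxel time series as baseline (100) +
category patterns (Gaussian, s.d. `pattern_amp`) scaled by per-condition
*separability* multipliers and convolved with a gamma HRF + per-condition
univariate amplitudes + per-run quadratic drift + motion-coupled nuisance
+ AR(1) noise (marginal s.d. `sigma`, coefficient `phi`). Separability 0
removes all category information from a condition by construction.

`simulate_event_bold()` drives each voxel with (centered parallelism x
voxel beta + luminance/contrast couplings + unmodulated amplitude) x the
ROI's HRF profile. The HRF enters as the piecewise-linear interpolation
of the gamma HRF sampled at the 2 s lag grid, zero outside 0-12 s,
matching the tent basis exactly: the deconvolution model is then exactly
identified, so noise-free recovery of the injected lag profiles to 1e-8
is a meaningful correctness check rather than an approximation statement.
The mean-centering of the parametric values in the generator matches the
analysis design matrix for the same reason. Real HRFs have tails beyond
12 s; that mismatch is a property of the tent model itself and is
deliberately excluded from the generator.

Default noise (`sigma = 1` percent signal, `phi = 0.3`) was fixed once at
a level giving mid-range decoding accuracies for a weakly separable
condition (neither floor nor ceiling) in a pilot of the block simulator,
and is the "stated SNR" of the acceptance checks. Real BOLD SNR varies
widely; these defaults are a desk-scale stand-in, not an empirical claim.

## Decoding pipeline (block data)

Per run: percent signal change about the voxel's run mean, then OLS
residuals against an intercept plus the 6 motion parameters. Residuals
are averaged over each block's volumes with a rigid 4 s (2 TR)
hemodynamic delay. Within each ROI, leave-one-run-out decoding trains a
linear one-vs-one SVM (dual coordinate descent, C = 1; no SVM package is
available in the target environment, so the solver is implemented
in-package) per condition. Voxel selection ranks voxels by the one-way
ANOVA F of activity across categories and picks the proportion (grid
0.1-1.0) maximizing inner leave-one-run-out accuracy, computed strictly
within the training runs of each outer fold; ties go to the larger
proportion. Group statistics are two-sided paired t-tests per ROI
(most vs least) with Benjamini-Hochberg FDR across ROIs; the directional
prediction is handled in reporting, not by one-sided tests. Univariate
condition means are block-averaged percent signal change (labeled as
such; whether the original univariate figures came from a separate GLM is
not specified).

## Model-based analysis (event data)

OLS per voxel on the tent design matrix gives 7 lag betas per parametric
regressor with standard errors. ROI summaries: unweighted voxel-mean beta
course, 4th-degree polynomial fit over the lags, and the area under that
polynomial integrated analytically on 2-10 s. Peak latency is the mode
`(k - 1) * theta` of a gamma `A * t^(k-1) * exp(-t/theta)` fitted to the
7 (lag, beta) points by least squares; `A` is profiled out analytically
and `(k, theta)` optimized from a fixed grid of starts with bounds
`k` in (1, 20], `theta` in (0.1, 10]. No additive baseline is fitted —
deconvolved betas are already baseline-referenced; fits with modes
outside 0-12 s, all-zero courses, or no converged start are flagged
invalid. The latency "bootstrap" is repeated voxel **subsampling without
replacement** (the source samples "50 percent of the voxels", which is a
subsample, not a classical bootstrap): per replicate, each ROI's sampled
beta courses are averaged, gammas fitted (warm-started from the full-ROI
fit), and the mode ordering per ROI pair recorded; invalid fits are
skipped and counted. The *fixed-count* scheme samples the same absolute
number of voxels from every ROI — half the size of the smallest ROI,
which is 828 for the published ROI size table (V4, 1656 voxels). The
per-voxel significance map uses the joint F-test of the 7 parallelism
betas (the statistic behind the source's map is unstated; this is the
declared choice), default alpha 0.001 uncorrected.

Within a single dataset the subsample modes concentrate around that
dataset's chance asymmetry, so "identical HRFs imply proportion 0.5"
holds only in expectation across datasets; the tests check
complementarity of the two orderings and absence of systematic direction
across independent datasets instead.

## Desk-scale acceptance checks

The published headline statistics (decoding difference p = 0.0018 in the
scene-selective ROI; earlier V4 peak in >99.6% of samples) depend on
unreleased subject data and a large public dataset, and are not
reproduced. The acceptance suite instead verifies what is derivable from
printed design facts plus construction: 475 drawings x 3 versions = 1425
images; 1503 volumes per participant; 828-voxel fixed-count subsamples;
oracle equivalence (distance transform, ANOVA F, BH, tent columns);
scoring/splitting invariants; parameter recovery (1e-8 noise-free betas,
0.5 s gamma-mode recovery, ordering proportion > 0.95 under both schemes
with a 2 s injected latency advantage); and a 100-replication group study
(5 subjects, 2 ROIs, 24 voxels/ROI — sizes chosen for the stated compute
budget) in which the most > least decoding difference must be significant
(BH q < 0.05, correct direction) in the designated ROI and not in the
control ROI in at least 95 replications. The control ROI is an exact
null, so about 2.5% of replications are expected to show a spurious
directional difference; 95/100 leaves room for that.

## Limitations

* The scoring parameters (`W`, `epsilon`, score map, flux threshold) are
  declared defaults, not values recovered from the original
  implementation; rankings are robust to them, absolute averages are not.
* The medial axis is computed on the pixel grid; no sub-pixel or exact
  polygonal (Voronoi) axis, and no pruning beyond the flux threshold.
* Voxels are abstract rows with ROI labels; NIfTI export lays ROIs out in
  disjoint slabs for interchange, with no real anatomy.
* GLS/prewhitening, spatial correction, and searchlight analyses are out
  of scope.
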