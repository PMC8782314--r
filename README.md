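# ribbonsym

Local parallelism — pairs of contours that keep a constant separation,
like the sides of a road or a tree trunk — is a mid-level perceptual
grouping cue in scene perception. `ribbonsym` implements an
image-computable measure of it for line drawings and the two fMRI
analyses built on that measure, with synthetic-data generators so the
whole pipeline runs and is tested without any external data.

**For whom:** vision scientists who want to score or manipulate the
parallelism content of line-drawing stimuli, and fMRI methodologists who
want a compact, fully tested reference for block-design MVPA decoding and
tent-basis (FIR) deconvolution with latency bootstrapping.

## The measure

The medial axis of the white space between contours is the locus where
the gradient of the Euclidean distance transform is multi-valued; each
axis point carries the radius `R`, its distance to the contours on either
side. Parallel contours have constant `R` along the axis. Each axis point
gets a ribbon-symmetry score

```
sigma = 1 - n / (W_eff - 1),    n = #{ |R(i+1) - R(i)| > epsilon }
```

counted in a `W`-point window along its branch (defaults `W = 11`,
`epsilon = 0.5` px), and each contour pixel takes the **maximum** of the
scores flowing to it from the skeletons on its two sides. The mean score
over all contour pixels is the image's parallelism rating. Rank-ordering
contour pixels by score and cutting at the median yields most- and
least-parallel half-images with exactly equal pixel counts.

Downstream analyses:

* **Decoding (block design):** percent signal change, motion-nuisance
  regression, block averaging at a 4 s hemodynamic delay, nested
  ANOVA-F voxel selection, leave-one-run-out linear SVM per image
  condition, paired t-tests with Benjamini-Hochberg FDR across ROIs.
* **Model-based GLM (event design):** 7-parameter tent deconvolution
  (0-12 s, TR = 2 s) of parallelism-modulated BOLD with luminance and
  contrast covariates; ROI beta courses, 4th-degree polynomial and
  2-10 s AUC summaries; gamma fits whose mode `(k-1)*theta` is the peak
  latency; 50%-subsample and fixed-count (828-voxel rule: half the
  smallest ROI) latency-ordering bootstraps.

## Worked example

```r
library(ribbonsym)

d  <- generate_drawing(drawing_spec(n_ribbons = 2, n_wedges = 1,
                                    n_curves = 1, canvas = c(256L, 256L)),
                       seed = 7)
d
#> <line_drawing> 7 contour(s) on 256x256 canvas

sm <- score_drawing(d)       # rasterize -> EDT -> medial axis -> score
sm
#> <contour_score_map> 773 contour pixel(s), mean score 0.901

average_parallelism(sm)
#> [1] 0.901

split_half(sm, seed = 7)
#> <split_pair> intact 773 px = most 387 px (mean 1.000) + least 386 px (mean 0.801)
```

The drawing has 7 contours: two exactly parallel ribbon pairs (4
contours, every pixel scores 1), one wedge and one random curve (scores
below 1). The image rating 0.901 is the mean pixel score. The split puts
the 387 highest-ranked pixels (all scoring 1.0 on average) into the
most-parallel half and the 386 lowest (mean 0.801) into the
least-parallel half; the two halves are disjoint, union to the intact
drawing, and differ in size by at most one pixel.

A command-line wrapper covers the file-based workflow
(`inst/cli/ribbonsym.R`): `rasterize`, `score`, `split`, `simulate`
subcommands over JSON drawings, plain-text PBM rasters, CSV scores, and
NIfTI exports of simulated datasets.

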