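Package: ribbonsym
Title: Local Parallelism Scoring of Line Drawings and Model-Based fMRI Analyses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores local parallelism (local ribbon symmetry) of line drawings
    via the medial axis transform of the inter-contour white space, splits
    drawings into most- and least-parallel half-images with equal contour
    pixel counts, and provides the two fMRI analyses that consume these
    scores: multivoxel scene-category decoding from block-design data
    (percent signal change, nuisance regression, nested ANOVA-F voxel
    selection, leave-one-run-out linear SVM, group statistics with FDR
    control) and tent-basis deconvolution of parallelism-modulated
    event-related BOLD with gamma-mode latency estimation and voxel
    subsampling ("bootstrap") latency comparisons. Includes synthetic-data
    generators for line drawings with known parallelism structure and for
    block- and event-design BOLD data with known ground truth, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
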