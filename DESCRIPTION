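Package: growthshape
Title: Shape-Based Mining of Bacterial Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters bacterial growth curves (OD600 time series) by shape
    similarity using a weighted combination of dynamic time warping (DTW)
    and derivative dynamic time warping (DDTW), with two cluster-number
    selection rules: a silhouette-based "reverse elbow" on an (alpha, n)
    grid, and a replicate-coherence rule that favours partitions keeping
    experimental replicates together. Includes stationary-phase truncation
    and viability filtering, replicate-variance data cleaning by
    top-quantile distance thresholds, hypergeometric over/under-
    representation tests of gene categories with Benjamini-Hochberg FDR
    control, a Gompertz/logistic parametric baseline, and a synthetic
    growth-curve generator with planted shape classes and category
    enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
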