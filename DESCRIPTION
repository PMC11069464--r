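Package: warpclust
Title: Dynamic-Time-Warping Clustering of Time Series with Lower-Bound Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering of equal-length univariate time series under the
    dynamic time warping (DTW) distance, accelerated by exact LB_Keogh
    lower-bound pruning. Provides a self-organizing map and a k-means
    engine whose best-matching-unit and centroid-assignment searches
    prune candidates with an Euclidean upper bound and an envelope-based
    lower bound without ever changing the result, together with pruning
    instrumentation, six external clustering-agreement indices, a seeded
    synthetic dataset generator, readers and writers for the tab-separated
    labelled archive dialect, and a stage that turns temporal-reference
    tagged conversation transcripts into decile "narrative arc" series
    ready for clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
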