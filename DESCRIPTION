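Package: respclust
Title: Unsupervised Shape-Based Classification of Respiratory Airflow Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the unsupervised, shape-based analysis of nasal airflow
    recorded by plethysmography. Respiratory cycles are segmented from the
    detrended lung-volume trace, inspiration and expiration sequences are
    clustered with dynamic time warping (DTW) K-means using batch stochastic
    DTW barycenter averaging (BS-DBA) centroids, and whole recordings are
    symbolized against the learned reference shapes with quantile-based
    outlier gating. Includes referent-cycle maps, RC heat maps, polar
    profiles and bar-code timelines, plus per-class Mann-Whitney comparisons
    with false discovery rate control, and a synthetic airflow generator with
    ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dtw.R'
    'barycenter.R'
    'clustering.R'
    'serialize.R'
    'symbolization.R'
    'stats.R'
    'visualization.R'
    'config.R'
    'signal_io.R'
    'segmentation.R'
    'synthetic.R'
    'cli.R'
    'respclust-package.R'
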