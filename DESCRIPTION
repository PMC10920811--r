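Package: bandcov
Title: Subject-Independent EEG Decoding from Band-Limited Spatial Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for subject-independent classification of multichannel EEG
    from the spatial covariance structure of band-limited oscillations.
    Implements three decoding pipelines over a seven-band filter bank
    (4-24 Hz): supervised spatial projection (common spatial patterns) with
    log-variance features, unsupervised projection (PCA) with Riemannian
    tangent-space vectorization of SPD covariance matrices, and handcrafted
    multitaper relative-power features with gradient-boosted trees.
    Includes a synthetic EEG cohort generator with a linear forward model and
    planted band-specific group effects, leave-subjects-out fold construction
    with validation-subject tuning, filter-to-pattern conversion for
    interpretable topographies, Shapley-value feature attributions, and
    cluster-based permutation statistics on sensor-space band power.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
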