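Package: touchdecode
Title: Decoding and Representational Analysis of Trial-Structured Intracortical Touch Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-unit intracortical recordings from
    trial-structured visuotactile touch experiments. Provides a synthetic
    session generator with planted, recoverable structure (condition gains,
    response latencies, shared channel noise covariance); multi-unit
    threshold-crossing extraction and baseline normalization; pairwise and
    cross-condition generalization decoding with SVD dimensionality reduction,
    linear discriminant classifiers and shuffled-label permutation nulls;
    cross-validated Mahalanobis (crossnobis) representational dissimilarity
    matrices with multivariate noise normalization and metric-stress MDS
    embeddings; per-channel condition-tuning regression with Bonferroni-Holm
    correction, bootstrap tuned-channel counts and response onset/offset
    latency estimation; and a seeded end-to-end pipeline with a recovery
    scorecard against the planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
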