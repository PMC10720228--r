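Package: hcfc
Title: Higher-Criticism Analysis of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical group-difference testing for cognition-related
    functional connectomes. Builds Fisher z-transformed Pearson connectivity
    matrices from parcel time series, fits one linear model per connection
    with group, sex, age and head-motion covariates, and tests for rare-weak
    group effects with the Higher Criticism statistic at three spatial
    scales (global, within-network, between-network) before resolving
    individual connections with Benjamini-Hochberg FDR. Includes parcel-level
    confound regression and band-pass denoising, a sliding-window dynamic
    connectivity state analysis (k-means with correlation distance, cluster
    number selection by Calinski-Harabasz and Davies-Bouldin indices, dwell
    time and transition metrics), and a synthetic-cohort generator that
    plants rare-weak effects and hidden switching covariance states for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
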