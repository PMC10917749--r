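Package: temporsa
Title: Time-Resolved Representational Similarity Analysis with Variance
    Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to order the emergence of scene representations in epoched
    multi-channel neural recordings. Implements time-resolved pairwise
    linear-discriminant decoding into representational dissimilarity matrices
    (RDMs), model RDM construction from feature matrices and from
    navigational-affordance angular histograms, nested-regression variance
    partitioning of neural RDMs into per-model unique variance timecourses,
    and group-level inference (FDR-corrected timepoint tests, bootstrap peak
    latencies with confidence intervals, paired peak comparisons). A
    synthetic-data generator injects known representational geometries at
    chosen latencies so the full pipeline can be validated without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
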