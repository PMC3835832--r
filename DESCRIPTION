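Package: cnmf
Title: Subgroup Discovery from DNA Copy-Number Profiles by Compacted
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers subgroups of patients from discrete DNA copy-number
    (and copy-neutral LOH) profiles.  Probe-level calls are encoded as a
    two-channel non-negative matrix, similar columns are merged into bins by
    Hamming distance under a genomic locality window, and the compacted
    matrix is factorized by Kullback-Leibler multiplicative-update NMF so
    that the divergence to the full, uncompacted matrix is what is being
    minimized.  Many seeded restarts are aggregated into a consensus
    (co-clustering) matrix, cut by hierarchical clustering; the number of
    subgroups is chosen with intra-cluster-similarity, cophenetic and
    silhouette measures, and cluster-label associations with external
    categorical annotations are assessed by an exact contingency-table test.
    Includes a synthetic copy-number profile generator with planted
    subgroups for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    cluster,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
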