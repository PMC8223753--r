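Package: mdnmtf
Title: Modularity-Preserving Matrix Tri-Factorization for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts novel miRNA-disease associations by jointly
    factorizing a miRNA similarity network, a disease similarity network
    and a known association matrix with a non-negative matrix
    tri-factorization model regularized by dynamic nearest-neighborhood
    graph Laplacians. Builds disease semantic similarity from a MeSH-style
    term hierarchy, disease functional similarity from gene evidence,
    miRNA functional similarity from associated-disease sets, and Gaussian
    interaction-profile kernels as fallbacks. A module-based extension
    extracts soft miRNA and disease modules from the learned latent
    factors and propagates known associations through them. Includes
    randomly-zeroing and single-column (cold-start) cross-validation
    harnesses with leakage-safe per-fold similarity recomputation, and a
    planted-module synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
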