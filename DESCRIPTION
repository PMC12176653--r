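Package: organoidmap
Title: Morphometric Profiling, Phenotype Mapping and Potency Estimation
    for Branched Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative phenotyping of branched (ductal-network)
    organoids from brightfield-style images. Provides a seeded synthetic
    organoid generator with exact ground truth for eight morphological
    families, skeleton-graph morphometrics (branch nodes, endpoints,
    terminal end buds, spiky branches, lumens, core geometry), a rule-based
    phenotype classifier, an image-feature embedding and clustering chain
    (features, PCA, t-SNE, elbow-selected k-means, per-group kernel density
    overlays), phenotype-composition shift statistics, dose-response
    AUC/GI50 summaries, single-hit Poisson limiting-dilution potency
    estimation with confidence intervals and a slope adequacy test, and
    phenotype gene-signature derivation (one-vs-rest negative binomial Wald
    tests with Benjamini-Hochberg correction) with rank-based recovery-curve
    AUC activity scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    Rcpp,
    Rtsne,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
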