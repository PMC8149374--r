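Package: ramanmark
Title: Multivariate Analysis of Raman Hyperspectral Tissue Maps for
    Vascular Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to discover disease-specific spectral biomarkers in
    Raman hyperspectral maps of vessel-wall tissue. Provides a synthetic
    generator of layered aortic-wall maps with known ground truth,
    spectral preprocessing (cosmic-ray removal, asymmetric least squares
    background subtraction, fingerprint cropping, intensity
    normalization), reference-seeded non-negative unmixing with abundance
    heatmaps, NIPALS principal-component analysis with per-animal score
    aggregation, sparse (l1-regularized) multivariate curve
    resolution-alternating least squares (MCR-ALS) with cross-validated
    regularization and warm-start transfer between cohorts, and a
    normality-gated group-comparison pipeline with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
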