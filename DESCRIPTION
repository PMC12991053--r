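Package: bcpseg
Title: Bayesian Changepoint Segmentation of Binned Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sensitive segmentation of copy-number profiles from low-pass
    (liquid biopsy) whole-genome sequencing. Implements the Barry-Hartigan
    product-partition changepoint model with a Gibbs-sampling approximation
    to obtain per-bin posterior changepoint probabilities, followed by
    probability filtering, peak detection, median-based segment
    reconstruction and merging of segments whose medians differ by less
    than a chosen multiple of the noise scale. Includes an exact
    enumeration oracle for small inputs, a simulator of purity-diluted
    copy-number profiles with multiplicative copy-number-dependent noise,
    and changepoint-detection metrics (precision, recall, F1 with a
    tolerance-window matching rule, and normalized mutual information
    between segmentations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
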