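Package: octlongreg
Title: Longitudinal Registration and Sector Analysis of Retinal Nerve
    Fiber Layer Thickness Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of peripapillary retinal nerve
    fiber layer thickness (RNFLT) maps measured by optical coherence
    tomography. Implements two similarity-transform registration algorithms
    for en-face fundus images: an automatic mutual-information grid search
    and a semi-automatic log-polar transform cross-correlation on segmented
    blood-vessel masks. Provides vessel-overlap precision/recall evaluation
    of registration quality, computation of the 17 standard RNFLT sector
    features (all-rings average, TSNI quadrants, 12 clock hours), linear
    mixed-effects models for longitudinal trend and paired-comparison
    analysis, and a synthetic-data generator producing vessel trees,
    fundus-like images, polar thickness maps, and jittered longitudinal
    series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
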