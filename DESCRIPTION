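Package: druseg
Title: Dense Residual U-Net Segmentation of Pulmonary Arteries in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based 3D segmentation of contrast-enhanced pulmonary
    arteries in thoracic CT. Implements a dense residual U-Net (DRU-Net)
    encoder-decoder with group normalization and leaky rectification, a
    hybrid Dice + binary cross-entropy (DBCE) training objective, Hounsfield
    unit windowing and patch extraction, probability-fusion reconstruction
    with connected-component filtering, Dice and 95th-percentile Hausdorff
    (mm) evaluation, k-fold cross-validation orchestration, and a synthetic
    vascular CT phantom generator so the full pipeline can be exercised
    without clinical data. Volumes are read and written as NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
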