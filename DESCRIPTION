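Package: smcoloc
Title: Two-Color Single-Molecule Colocalization Immunoassay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-color single-molecule sandwich
    immunoassays imaged by TIRF microscopy. Detects diffraction-limited
    capture- and detection-antibody spots in stitched two-channel frames,
    estimates the inter-channel affine registration from fiducial bead
    images, counts colocalized antibody pairs under a pixel-distance
    criterion with capture-antibody normalization, fits Langmuir
    calibration curves with limit-of-detection error propagation,
    quantifies concentration-prediction error by out-of-bag bootstrap
    (mean absolute percentage log error), and scores target detection by
    bootstrapped logistic-regression ROC/AUC. Includes a synthetic
    two-color image generator with known ground truth and a Monte-Carlo
    model of false colocalization from non-specific binding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
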