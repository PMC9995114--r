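Package: fibsemqc
Title: Quality Assessment and Calibration for Serial FIB/SEM Volume Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative quality-control procedures for serial focussed ion
    beam / scanning electron microscopy (FIB/SEM) volume imaging of vitrified
    biological samples. Implements Fourier-wedge curtaining scoring with
    minimum cross-entropy thresholding, two-image and calibrated one-image
    Fourier ring correlation (FRC) local-resolution mapping, depth-of-field
    estimation from through-focus series, suppression of SEM charging
    artifacts by row-wise sigmoid-tail fitting, bead-based milling-step (Z)
    calibration from sphere cross-section areas, stage-drift and shape
    metrics, electron-dose calculation, and 3D organelle and membrane
    contact-site quantification on label masks. Includes seed-deterministic
    synthetic-data generators with ground truth for validating every
    procedure, TIFF and MRC2014 stack IO, and a command-line interface.
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
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
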