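Package: stiffgrad
Title: Closed-Loop Microfluidic Stiffness Gradients with Image-Based Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for deep-learning-assisted
    generation of hydrogel concentration gradients in droplet microfluidics.
    Provides seeded synthetic generators for laminar co-flow junction images,
    fluorescent alginate bead fields and bright-field spheroid fields; a
    shallow convolutional network that classifies the laminar interface
    position together with a Canny edge-detection baseline; a simulated
    co-flow plant with viscosity-dependent pump lag and per-droplet
    compositional bookkeeping; the closed-loop controller state machine that
    alternates volume-fraction targets with an overshoot phase; and a
    high-content quantification pipeline (single-stage grid detector,
    fluorescence-to-concentration and concentration-to-stiffness
    calibrations, spheroid measurement and binned dose-response statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    data.table,
    minpack.lm,
    yaml,
    jsonlite,
    png,
    tiff,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'calibration.R'
    'detector.R'
    'assay.R'
    'canny.R'
    'synthfix.R'
    'interfaceClassifier.R'
    'plant.R'
    'controller.R'
    'pipeline.R'
    'stiffgrad-package.R'
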