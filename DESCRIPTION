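Package: capnonet
Title: COPD Detection and Severity Grading from Volumetric Capnography
    via Gramian Angular Field Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that turns volumetric capnograms
    (exhaled CO2 concentration versus cumulative exhaled volume) into
    two-dimensional Gramian Angular Field (GASF/GADF) grayscale images and
    classifies them with CapnoNet, a compact multi-scale (inception-style)
    convolutional neural network, to detect chronic obstructive pulmonary
    disease (COPD) and grade airway-obstruction severity (GOLD 1-4).
    Includes a synthetic three-phase capnogram simulator with
    severity-dependent phase II/III morphology, breath-level signal
    preprocessing (resampling, zero-phase Butterworth filtering, exhalation
    segmentation, volume-domain conversion, piecewise aggregate
    approximation), a Gaussian-noise plus elastic-deformation augmentation
    policy, parameter and FLOP accounting for the network, and a stratified
    subject-level k-fold cross-validation harness. The neural network
    (convolution, batch normalization, pooling, dropout, Adam optimization)
    is implemented in base R on BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
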