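Package: needletrack
Title: Multilateration-Based 3D Needle-Tip Tracking for Sparse-Array Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ultrasonic needle-tip localization with a sparse 2D
    matrix-array probe and a point-like hydrophone receiver at the needle tip.
    Implements linear-chirp and Gaussian tone-burst excitation synthesis, an
    acoustic point-source propagation simulator with sub-sample delays,
    zero-phase bandpass filtering, matched-filter pulse compression and
    envelope detection, reliability-gated time-of-arrival estimation,
    Gauss-Newton multilateration with a closed-form linearized initializer,
    a one-way delay-and-sum volumetric baseline with center-of-mass
    localization, Fermat's-spiral array generation with inner-to-outer
    sparsification, an acquisition frame-rate model, SNR measurement, and
    Monte-Carlo sparsification sweeps comparing both localization methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    graphics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
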