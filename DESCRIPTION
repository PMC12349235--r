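Package: stormmcg
Title: Unshielded Magnetocardiography Signal Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for multichannel magnetocardiography (MCG)
    recorded outside a magnetically shielded room with a magnetoresistive
    sensor array: zero-phase bandpass and notch filtering, adaptive noise
    cancellation driven by dedicated reference sensors, ECG R-peak
    synchronized epoch averaging, interference suppression by constrained
    maximum-likelihood factor analysis (Bayesian signal-space projection),
    signal-to-noise quantification, and isomagnetic field mapping.
    Includes a synthetic-session simulator (current-dipole cardiac source,
    low-rank environmental interference, matched empty-room noise) with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
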