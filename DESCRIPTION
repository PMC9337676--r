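Package: bcghrv
Title: Contactless Heart Rate and HRV Estimation from Chair Ballistocardiograms
Version: 0.1.0
Authors@R:
    person("BCG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating beat-to-beat heart rate and heart-rate
    variability (HRV) from four-channel chair load-cell ballistocardiogram
    (BCG) recordings. Implements windowed amplitude quality control,
    zero-phase Butterworth band-pass filtering, extrema-candidate extraction,
    a small one-dimensional convolutional network that regresses the ECG
    R-peak time from 3-second BCG windows, physiology-based RR-interval
    quality flagging and channel selection, time- and frequency-domain HRV
    features, tolerance-based epoch validation with leave-one-subject-out
    cross-validation, and a physics-based paired BCG+ECG simulator (aortic
    force model, Wheatstone-bridge load-cell electronics, respiration,
    baseline drift and motion artifacts) so the whole pipeline is testable
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
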