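Package: scgbeat
Title: Heartbeat Detection and Heart-Rate Estimation from Tri-Axial
    Seismocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for heartbeat detection and heart-rate
    estimation from tri-axial seismocardiography (SCG) recordings:
    zero-phase high-pass filtering and robust median-based amplitude
    scaling, construction of per-sample heartbeat masks from reference
    RR intervals, a 1D encoder-decoder (U-Net style) segmentation
    network trained with class-weighted cross-entropy, rule-based beat
    localization from predicted probability masks, inter-beat-interval
    correction and quality-gated sliding-window heart-rate estimation,
    spectral-energy movement-artifact flagging, and tolerance-based
    detection scoring with Bland-Altman agreement analysis. Includes a
    seeded synthetic SCG simulator (quasi-periodic beat wavelets,
    respiration, sensor noise, dual-peak morphology, motion bursts) so
    the whole pipeline is testable without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
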