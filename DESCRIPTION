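Package: wormtrace
Title: Single-Frame Detection and Analysis of Complex C. elegans Postures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generative coarse-to-fine statistical detection of Caenorhabditis
    elegans postures from single grayscale microscopy frames, including
    non-self-avoiding (coiled, spooled, omega-shaped) configurations.
    Oriented binary edges feed likelihood-ratio tests for mid-level head,
    body and double-body features on a coarse grid; a head-first beam search
    finds the maximum a posteriori coarse midline; dynamic programming
    refines the body boundaries at pixel resolution. A posture-analytics
    layer provides the 18-relative-angle representation, coil detection,
    eigenworm principal-component analysis, posture clustering, locomotion
    state classification, coil-event statistics and transition-aligned
    summaries. A synthetic scene generator renders worms with ground truth
    so every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
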