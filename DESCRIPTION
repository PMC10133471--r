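Package: gdneteeg
Title: Group Depth-Wise Convolutional Networks with EEG Attention for
    SSVEP Stimulation-Frequency Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state visually evoked potential (SSVEP)
    stimulation-frequency recognition from multi-channel EEG. Implements a
    convolutional architecture built on group depth-wise convolution (one
    learned temporal kernel per EEG channel per feature-map pair) together
    with a two-stage EEG attention module (per-electrode channel-wise gates
    and per-feature-map network-wise gates), a synthetic SSVEP trial
    generator covering a 40-target frequency/phase-coded paradigm, Chebyshev
    Type I band-pass preprocessing, segment-level training with Adam and L2
    regularisation, stratified grouped k-fold evaluation with
    accuracy/sensitivity/specificity reporting, ablation-variant builders,
    electrode-montage subset selection, and a command-line interface. The
    network forward and backward passes are implemented in R on top of BLAS
    matrix products and are validated against brute-force convolution
    oracles and numerical gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    R.matlab
Config/testthat/edition: 3
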