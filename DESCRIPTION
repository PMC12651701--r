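Package: eegnetkit
Title: Low- and High-Order EEG Functional Network Analysis with Dynamic
    State Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds static and dynamic functional brain networks from
    multichannel resting-state EEG recorded on a 16-channel 10-20 montage.
    Band-limited signals (delta, theta, alpha, beta) are obtained by
    Daubechies-4 wavelet decomposition, amplitude envelopes by the Hilbert
    transform, low-order connectivity as absolute envelope correlations and
    high-order connectivity as correlations between Fisher-z-transformed
    connectivity profiles.  Weighted graph metrics (nodal and global
    efficiency, nodal and average clustering) are computed per band, and
    non-overlapping windowed networks yield integrated/segregated state
    sequences whose transition-pattern entropy quantifies dynamic network
    reorganization.  A seeded synthetic-cohort generator with planted
    coupling structure and regime dynamics provides ground truth for
    validation, and paired pre/post statistics summarize condition effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
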