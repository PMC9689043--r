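Package: lusim
Title: Simulation of A-Line and B-Line Artifacts in Lung Ultrasonography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A 2D acoustic simulator of lung ultrasonography (LUS) artifact
    formation. Builds randomized inhomogeneous tissue phantoms (a muscle slab
    over a fluid-infiltrated subpleural "lung disease zone"), propagates
    pulses from a 32-element linear array with transmit focal delay laws
    through a staggered-grid finite-difference time-domain solver with
    lateral absorbing layers and a pressure-release pleural boundary, records
    per-element radio-frequency traces, and composes log-compressed
    envelope-detected B-scan images that reproduce horizontal A-line
    reverberation bands and vertical B-line comet-tail artifacts. Includes
    quantitative artifact metrics (echo-train detection, B-line intensity
    ratio and lateral width) and an experiment runner for parameter sweeps
    over domain geometry and tissue inhomogeneity level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
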