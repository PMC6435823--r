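Package: azquant
Title: Single Active-Zone Channel Quantification and Optical Quantal Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification of voltage-gated calcium channel abundance at
    individual presynaptic active zones of the Drosophila larval
    neuromuscular junction, and its relationship to single-synapse
    release probability and homeostatic plasticity. Implements fluorescent
    punctum detection and segmentation (Gaussian smoothing, background
    subtraction, tolerance-based local-maximum segmentation, mask transfer
    across channels and timepoints), optical quantal analysis (stimulus-locked
    event detection in movies, nearest-neighbour assignment of events to
    active zones, per-active-zone release probability estimation and
    intensity correlation), paired before/after intensity analysis with
    vehicle correction and additive-versus-multiplicative scaling
    discrimination, ratiometric calcium-transient analysis with robust
    outlier exclusion, and quantal analysis of intracellular recordings.
    A fully seeded synthetic-data generator produces every input with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    sandwich
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Neuroscience
RoxygenNote: 7.3.3
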