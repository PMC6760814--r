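Package: fishrules
Title: Learning Interaction Rules of Collective Motion with Attention Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns pairwise interaction rules and neighbour-weighting rules of
    collective animal motion from multi-individual trajectory recordings. A
    constrained two-module attention network predicts the turning side of a
    focal individual from the kinematics of its nearest neighbours; the trained
    pair-interaction module is mapped into attraction, repulsion, alignment and
    anti-alignment regions, and the entropy of the attention weights yields an
    effective number of interacting neighbours. Includes a zonal
    (repulsion/orientation/attraction) agent-based simulator that provides
    ground-truth trajectories for validating rule recovery, together with
    trajectory preprocessing (gap interpolation, arena normalization, causal
    smoothing, causal finite differences) and a circular-shift shuffle control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    zoo,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
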