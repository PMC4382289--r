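Package: reflexgait
Title: Predictive Simulation of Human Walking with Reflex-Based Muscle Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A planar neuromusculoskeletal simulation framework for predictive
    gait synthesis. A 7-segment, 9 degree-of-freedom sagittal-plane skeleton is
    driven by 8 Hill-type musculotendon units per leg, excited by delayed force,
    stretch, and proportional-derivative reflex laws switched by a per-leg gait
    mode state machine. Foot-ground interaction uses compliant Hunt-Crossley
    spheres with smooth Stribeck friction. Controller parameters and initial
    conditions are optimized with a covariance matrix adaptation evolution
    strategy (CMA-ES) against a fall/velocity/head-stability/effort objective,
    producing emergent gaits for normal, loaded, and inclined walking. Includes
    muscle metabolic energetics, stride-cycle gait analysis, reference-band
    coverage scoring, and Teager-Kaiser EMG onset detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
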