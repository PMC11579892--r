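Package: synid
Title: Muscle-Synergy Based Intention Decoding for Center-Out Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes the direction of center-out reaching movements from
    surface electromyography (EMG). Raw multi-muscle EMG is reduced to causal
    linear envelopes, muscle synergies are extracted offline by non-negative
    matrix factorization, and movement direction is decoded online by
    per-direction Gaussian mixture models combined through Bayesian evidence
    accumulation after an adaptive-threshold EMG onset detector fires. A
    simplified four-degree-of-freedom exoskeleton arm model provides
    virtual-stiffness assistance statics (Jacobian-transpose torques, gravity
    compensation, manipulability), and an evaluation layer computes confusion
    matrices, error-type taxonomies, modified accuracy over time, polar
    repeatability errors, integrated EMG, adjusted chance levels and a
    kinematics-based benchmark classifier. A seeded synthetic-session
    generator produces direction-tuned, synergy-driven envelopes and
    minimum-jerk trajectories so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
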