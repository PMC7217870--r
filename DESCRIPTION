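Package: emofmri
Title: Simulation and Analysis of an Event-Related Emotion-Appraisal fMRI Experiment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates fully seeded synthetic data for a 3 (benefactor-intention) x
    3 (benefit-value) x 2 (emotion: gratitude, joy) within-subject event-related
    fMRI design -- pseudo-randomized trial schedules, ordinal emotion ratings, and
    4D BOLD volumes with known condition amplitudes and parametric-modulation
    slopes -- and implements the full analysis pipeline: behavioral
    repeated-measures ANOVAs and planned paired comparisons; first-level GLMs
    with a canonical double-gamma haemodynamic response and serially
    orthogonalized parametric modulators; group-level interaction contrasts with
    Monte-Carlo cluster-extent family-wise-error correction; and
    leave-one-participant-out linear-SVM multivariate pattern analysis with
    within-fold feature selection, permutation inference, and consensus weight
    maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
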