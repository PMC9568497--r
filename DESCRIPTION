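Package: gazecue
Title: Gaze-Cueing Analysis of Detection Performance and Microsaccades
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for gaze-cueing experiments with
    concurrent eye tracking. Detects saccades, microsaccades and blinks
    from 1000 Hz gaze-sample streams with a velocity-threshold
    (lambda-times-robust-SD) criterion, tabulates signal-detection
    measures (hit rate, false-alarm rate, d-prime) and valid-minus-invalid
    cueing effects, computes microsaccade rate curves and cue-direction
    bias statistics, quantifies gaze information in annotation data with a
    permutation baseline, and performs hierarchical participant-level
    bootstrap inference with Benjamini-Hochberg false-discovery-rate
    correction. A synthetic-data generator produces fixational traces with
    ground-truth ocular events and signal-detection-governed behavioral
    trials so every stage is testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
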