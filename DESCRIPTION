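Package: afdm
Title: Atrial Fibrillation Driver Mapping from Multi-Electrode Catheter Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and characterization of atrial fibrillation drivers from
    multi-electrode (5-spline by 4-electrode) catheter recordings. Implements
    local activation time annotation on unipolar electrograms, dominant cycle
    length estimation, rotational-activity detection from staircase activation
    of concentric electrode rings, focal-activity detection from unipolar QS
    morphology, hidden-Markov-model scoring of bipolar electrical burden,
    non-rigid registration of left-atrial surface meshes with regional voltage
    analysis, and the cohort statistics linking driver location to
    post-ablation arrhythmia recurrence (contingency tests, logistic odds
    ratios, propensity-score matching). Includes a synthetic-data generator
    producing catheter geometries, activation fields, electrogram waveforms,
    atrial meshes, and confounded patient cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
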