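Package: optomaze
Title: Behavioral and Fiber-Photometry Analysis for Circular-Maze
    Optogenetics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for operant experiments on an eight-segment
    circular maze with four feeding stations, combined with optogenetic
    stimulation and wireless fiber photometry.  Parses timestamped maze
    event logs into laps and feeder choices; computes correct-response and
    rule-learning rates, lap counts and running speeds with their
    trial-shuffled chance distributions; builds peri-event time histograms
    of photometry signals as percent dR/R0 and Z-scores around stimulation
    onsets; classifies pose-derived locomotion into ambulation, immobility
    and fine movement by velocity thresholds; and provides mixed and
    repeated-measures two-way ANOVA with Greenhouse-Geisser correction,
    exact Wilcoxon tests and Bonferroni adjustment.  A synthetic-data
    module simulates a value-learning maze agent, burst-stimulation
    photometry traces and open-field pose tracks with known ground truth,
    so every stage of the pipeline can be exercised and calibrated without
    external recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
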