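Package: vibtrials
Title: Trial Analysis for Substrate-Borne Vibrational Playback Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for playback experiments on plant-borne
    vibrational communication. Represents the experimental plant as a metric
    tree of subsections and computes per-trial mate-search metrics (path
    efficiency, search ratio, approach, overall efficiency), groups annotated
    signal sections into signals and masking bouts, builds treatment playback
    schedules and temporal masking/overlap statistics, performs two-axis
    motion-ellipse transmission analysis with dB amplitude maps, simulates
    complete synthetic trials with known ground truth, and provides the
    mixed-model treatment-contrast and repeated-measures correlation layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
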