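Package: thalattn
Title: Spike-Train and Behavior Analysis for Cross-Modal Conditioning Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of head-fixed cross-modal conditioning
    sessions in which a tactile (air puff) and a visual (drifting grating)
    stimulus are presented on decorrelated, flat-hazard schedules and one
    modality predicts a water reward. Provides stimulus-schedule generators
    with a verifiable flat-hazard property, an inhomogeneous-Poisson session
    simulator with recorded ground truth (spikes, licking, pupil, whisking),
    lick-index learning metrics, pupil and whisker signal conditioning
    (blink removal, Hilbert-envelope whisking amplitude), single-unit quality
    control and spontaneous-rate estimation, response classification with
    Holm-Bonferroni control, a selectivity index with an anatomical-position
    linear model, response-latency detection, and regression-based
    movement-artifact correction of firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
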