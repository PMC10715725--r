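Package: foragekit
Title: Capture-Rate Foraging Models and Movement Vigor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how animals coordinate decisions with movements
    while foraging. Implements a normative capture-rate model of alternating
    work and harvest periods (reward earned by successful trials, consumed by
    effortful licks), with integer-grid and continuous optimal-policy solvers,
    an effort-dependent lick-duration cost, parameter sweeps for comparative
    statics, and a competing multiplicative utility. Provides a behavioral
    analysis pipeline: amplitude-velocity main-sequence fitting, per-movement
    vigor, saccade detection and classification, lick classification,
    work/harvest segmentation, event-locked pupil normalization, and the binned
    vigor, accuracy, and pupil summaries used to test the model's predictions.
    A synthetic-session generator with full ground truth supports parameter
    recovery testing throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
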