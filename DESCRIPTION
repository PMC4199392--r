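Package: tapgain
Title: Reverse Correlation of Motor Contributions to Rhythmic Auditory Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse rhythmic tone-categorization
    experiments in which listeners judge the mean pitch of beat-aligned target
    tones embedded among antiphase distractors, with or without overt motor
    tracking (finger tapping) of the beat. Provides a synthetic-data generator
    (tone sequences with controlled jitter regimes, tap trains with timing
    noise and misses, choices from a probit observer with phase-locked gain
    modulation and an adaptive staircase), probit reverse-correlation of
    choices on per-tone frequencies to estimate sensory gains, sensorimotor
    simultaneity phase analysis (delay correction, tap interpolation, sliding
    octile gain profiles, cosine/sine gain-modulation fits), and group-level
    statistics including an AIC-based Bayes factor and the Watson-Williams
    circular test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
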