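Package: cmcgait
Title: Corticomuscular Coherence, Motor-Preparation Beta Power, and Gait
    Analysis for Ankle Dorsiflexion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of ankle motor control that combine
    scalp EEG, surface EMG and ankle-angle recordings. Implements zero-phase
    preprocessing (notch, band-pass, full-wave rectification, EOG regression),
    movement-onset detection and epoching, segment-averaged magnitude-squared
    coherence between motor cortex (Cz) and tibialis anterior with the
    Rosenberg-style confidence level, complex Morlet wavelet beta-band
    (14-20 Hz) power time courses with baseline normalization and windowed
    motor-preparation features, biomechanical dorsiflexion and gait metrics,
    normality-gated two-group statistics with pooled-SD effect sizes, and a
    bootstrap-augmented support-vector-machine classifier that predicts
    coherence group from pre-movement beta power. A seeded synthetic-cohort
    generator reproduces the statistical structure of such a study so the
    whole chain can be validated without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    zoo,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
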