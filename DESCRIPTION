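Package: tausleep
Title: Longitudinal Rodent Sleep-EEG Analysis for Tauopathy Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis chain for longitudinal rodent polysomnography:
    synthetic EEG/EMG cohort generation with circadian Markov state dynamics,
    period-amplitude (half-wave) and band-power feature extraction from 10-s
    epochs, arousal-state staging by ranked membership against per-animal
    templates with EMG criteria, sleep bout and continuity metrics, artefact
    quality control with week-level exclusion, frame-differencing video
    locomotor activity, and longitudinal group contrasts (least-squares means
    with unstructured within-animal covariance, Tukey-Kramer adjustment and
    log-scale back-transform) plus terminal ANOVA and actual/residual Spearman
    correlation against brain atrophy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    emmeans,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
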