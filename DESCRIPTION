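Package: stressweek
Title: Detecting Prolonged Real-Life Stress from Momentary Self-Reports and
    Wearable Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates and analyses two-week naturalistic stress studies in
    which participants complete ecological momentary assessments (EMA) six
    times a day during one high-stakes examination week and one control week
    while wearing a wrist biosensor recording electrodermal activity, heart
    rate, skin temperature and movement. Provides a synthetic cohort
    generator with configurable true effect sizes, EMA scale scoring with
    compliance filtering and person-centering, electrodermal signal
    processing (despiking, denoising, elliptic low-pass filtering and
    tonic/phasic decomposition via a Bateman impulse response), per-beep
    physiological feature extraction, generalized linear mixed-effects
    modelling of week and momentary effects with FDR correction, mediation
    of arousal changes by positive affect with cluster bootstrap, and
    random-forest classification of beeps under leave-one-beep-out and
    leave-one-subject-out cross-validation with bootstrap null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    lme4,
    randomForest,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
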