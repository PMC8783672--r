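Package: arousalscape
Title: Detection, Typing and Correlates of Spontaneous Sleep EEG Arousals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the study of spontaneous arousals in overnight sleep
    EEG. Implements a two-step median-adaptive arousal detector operating on
    1-second band powers (lower-theta, broad-alpha and beta, with the sigma
    spindle range excluded), classification of detected events by sleep-stage
    transition (T+/T-) and electromyographic tone (M+/M-) status, Morlet
    wavelet spectral profiling of arousal onsets, per-subject sleep
    fragmentation metrics (hourly arousal indices, WASO, awakenings), and a
    mixed-model association layer linking arousal types to amyloid-beta
    burden and cognitive composites with semipartial R-squared effect sizes.
    A synthetic polysomnography and cohort generator with ground-truth
    arousals makes every stage of the pipeline testable without real
    recordings. Reads and writes EDF signals, plain-text hypnograms and CSV
    event/cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
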