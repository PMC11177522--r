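Package: spasmap
Title: High-Density Surface EMG Activation Mapping of Spastic Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-density surface electromyography
    (HD-sEMG) recordings from an 8x8 electrode grid over the biceps brachii,
    aimed at characterising spastic muscle activity after stroke. Provides
    signal preprocessing (notch and Butterworth band-pass filtering, bad
    channel detection and grid interpolation), task epoch extraction for
    passive isokinetic stretches and isometric contractions, normalised RMS
    (nRMS) activation maps with MVC-based normalisation, centre-of-gravity
    statistics, h-dome morphological segmentation of activation clusters,
    within- and between-task cluster overlap degrees, and the accompanying
    mixed-design ANOVA and t-test layer. Includes a calibrated synthetic
    cohort generator that emulates healthy and spastic activation profiles
    for end-to-end testing and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
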