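Package: odontoPulse
Title: Detection and Characterization of Odontocete Pulsed Vocalizations
    and Whistles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Passive-acoustic-monitoring pipeline for odontocete
    vocalizations. Detects broadband echolocation pulses with the
    Teager-Kaiser energy operator and a matched Gaussian/rectangular
    filter-difference-ratio score, groups pulses into trains with an
    adaptive inter-pulse-interval rule, classifies trains as echolocation
    clicks, burst pulses or buzzes, and measures per-pulse spectral and
    level parameters on hydrophone-calibrated audio. Also provides whistle
    contour feature extraction (thirteen standard characteristics, contour
    typing, SNR grading, harmonic detection), a calibrated synthetic-scene
    generator with exact ground-truth manifests for detector validation,
    and batch reporting in a per-train folder layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr,
    knitr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'wav.R'
    'audio_io.R'
    'pulse_detector.R'
    'train_builder.R'
    'signal_metrics.R'
    'whistle_features.R'
    'synthetic_scenes.R'
    'cli_reporting.R'
    'odontoPulse-package.R'
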