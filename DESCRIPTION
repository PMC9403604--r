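Package: vogdetect
Title: Nystagmus Detection from Video-Oculography by Recursive Filtered-Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects nystagmus (involuntary rhythmic eye oscillation) in short
    monocular video-oculography clips without eye tracking or calibration. A
    recursive temporal filter converts each clip into a stack of motion-energy
    "filtered images"; a small per-image classifier scores each image, and
    soft, hard-majority, temporal-run or ensemble voting aggregates the
    per-image probabilities into a video-level decision. Includes a parametric
    simulator of jerk and pendular nystagmus waveforms with blink, square-wave
    jerk and drift distractors, video degradation utilities (frame-rate
    decimation, area-average downscaling), and an evaluation harness with
    ROC analysis and patient-aware stratified k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
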