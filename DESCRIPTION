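Package: posturesim
Title: Forward-Dynamics Simulation of Human Standing with a Vestibulospinal Feedback Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamics simulation of quiet human standing with a
    neural controller that combines constant feedforward muscle tone
    (reticulospinal analogue), delayed proprioceptive feedback from muscle
    length and lengthening velocity, and delayed vestibular feedback that
    excites extensors and inhibits flexors (lateral vestibulospinal tract
    analogue).  Provides reduced sagittal-plane musculoskeletal plants
    (single-link and four-link chains with Hill-type muscle groups), Gaussian
    sensory noise with per-channel magnitude calibration, a two-stage
    parameter pipeline (muscle-tone candidate sweep followed by CMA-ES
    feedback-gain optimization of a fall/posture objective), and a sway
    analysis stack: anterior-posterior centre-of-pressure velocity,
    Lomb-Scargle power spectra with log-log slope estimates, tone-variability
    correlation, and Bonferroni-corrected condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
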