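Package: motionforecast
Title: Forward Prediction of Spatial Pattern from Visual Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for psychophysical studies of
    motion-induced forward prediction. Generates drifting sinusoidal grating
    displays, computes the interference profile produced by superposing a
    target with the extrapolated continuation of a moving inducer, simulates
    a calibrated two-alternative forced-choice observer whose contrast
    detection combines divisive surround suppression with additive predictive
    superposition, schedules method-of-constant-stimuli sessions, and fits
    logistic psychometric functions with bootstrap standard errors plus
    saturating and decaying exponential summaries of the interference effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
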