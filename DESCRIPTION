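Package: earforce
Title: Occlusal Force Estimation from Ear Canal Movement Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for estimating occlusal (bite) force from an
    earphone-type optical sensor that tracks ear canal deformation during
    chewing. Provides domain types for multi-channel AD-converted recordings
    (ear sensor, masseter EMG envelope, occlusal force meter), calibration of
    AD values to Newtons, per-run Pearson and first-order partial correlation
    summaries, a fold-averaged anchored single-regression force estimator
    evaluated by leave-one-run-out cross-validation with RMSE and NRMSE, and
    a seeded synthetic session generator emulating the press-and-hold chew
    protocol so the pipeline is testable without restricted subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
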