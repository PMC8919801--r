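Package: tapkin
Title: Kinematic Analysis of Finger-Tapping Landmark Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing finger-tapping performance from markerless
    hand-landmark time series, as used in video-based assessment of ataxia
    and parkinsonism. Provides quality control and signal conditioning for
    index-thumb distance traces (leave-one-out cubic outlier screening, gap
    interpolation, resampling, FIR low-pass filtering, z-scoring), tap
    event detection, a five-family kinematic feature inventory with
    per-cycle quadratic parameterisation, per-family principal component
    reduction, subject-grouped cross-validated classification and severity
    regression with penalised linear models, feature-contribution reports,
    and a synthetic cohort generator that emulates ataxic, parkinsonian and
    control tapping phenotypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
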