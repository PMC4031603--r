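Package: footroll
Title: Foot Rollover Analysis for Plantar Pressure and Gait Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the foot rollover process during the stance
    phase of barefoot walking from insole plantar-pressure recordings and
    synchronized marker/force-plate data. Provides regional plantar-pressure
    metrics (peak pressure, time-to-peak pressure, pressure-time integral,
    centre-of-pressure velocity) over the six standard anatomical foot areas,
    sagittal ankle kinematics and net ankle moments by bottom-up inverse
    dynamics, clinical foot-function scoring, and the intention-to-treat
    repeated-measures statistics used in two-arm exercise trials, together
    with synthetic-data generators with closed-form ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
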