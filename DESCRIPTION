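Package: freegait
Title: Gait Speed from Foot-Worn Inertial Sensors in Supervised and
    Free-Living Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-stride gait speed from a single foot-worn
    inertial measurement unit by strapdown integration with zero-velocity
    updates, segments free-living stride sequences into walking bouts,
    assigns medication states (ON / not-ON) from a dosing diary, and
    compares laboratory gait tests against at-home gait speed
    distributions with normality-gated paired tests and correlations.
    Ships a synthetic-data generator producing foot-IMU signals with
    analytically known stride speeds and full simulated patient days, so
    every pipeline stage is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
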