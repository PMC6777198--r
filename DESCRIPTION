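Package: aortadose
Title: Heart-Rate and Body-Surface-Area Based Contrast Dosing for CT
    Aortography, with a Simulated Three-Arm Study Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an injector-style contrast-agent dose calculator for
    CT angiography of the aorta that individualizes contrast volume from body
    surface area (45 ml per square metre) with piecewise heart-rate and iodine
    concentration corrections, dose clamping and an optional 50 percent
    dilution arm.  Around the calculator it provides a seeded simulation of a
    three-arm pilot study: truncated-normal cohort generation, per-patient
    aortic enhancement at five measurement levels, two-reader five-point
    visual grading with reader bias, a synthetic axial CT phantom with
    circular region-of-interest measurement, and the study statistics
    (descriptives, pooled and Welch t-tests, intraclass correlation of the
    consistency, average-measures form) needed to reproduce the study's group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
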