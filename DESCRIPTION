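Package: gyrokernels
Title: Seed Dispersal Kernels for Auto-Gyrating Winged Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling wind dispersal of auto-gyrating (samara-like)
    tree fruit from morphology. Computes inverse wing loading (long-wing area
    over fruit mass) and wing-loading unit conversions, fits a random-intercept
    linear mixed model of log dispersal distance on log inverse wing loading,
    log maximum wind speed and their interaction by profiled REML, performs
    parametric-bootstrap inference (percentile intervals and approximate
    p-values), simulates log-normal dispersal kernels with 95% confidence
    bands over a grid of inverse wing loading and wind speed, and evaluates a
    ballistic comparison model in which horizontal distance is wind speed
    times release height over terminal velocity. Includes a synthetic
    release-experiment generator emulating a 30-m canopy-tower release study
    of 13 dipterocarp species, so the full pipeline is testable without the
    original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
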