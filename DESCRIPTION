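Package: sdmblend
Title: Blending Community-Sourced and Survey Occurrence Records in Species
    Distribution Models
Version: 0.1.0
Authors@R:
    person("sdmblend", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for presence-only species distribution modelling with mixed
    provenance occurrence data. Implements quality filtering of community-sourced
    records driven by observer statistics, audit-based estimation of per-taxon
    record validity, bioclimatic predictor construction with PCA reduction, a
    MaxEnt-style penalized background-contrast model with linear, quadratic and
    hinge features, sampling-effort-weighted pseudo-absence selection, spatial
    block evaluation with the continuous Boyce index, and a blending experiment
    comparing survey-only against blended training data. Ships a synthetic data
    generator (virtual species on simulated landscapes with configurable observer
    error) so the whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
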