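Package: exposcan
Title: Exposome-Wide Association Screening for Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A screening pipeline for environment-wide association studies
    (EWAS) of lifestyle exposures against cardiometabolic traits in
    repeated-measures cohorts. Harmonizes raw cohort tables (medication
    corrections, derived traits, dietary-quality filters, rank-based
    inverse-normal transformation, dummy coding), screens hundreds of
    exposures against multiple traits with a random-intercept linear mixed
    model fitted by REML (average associations) and a baseline-adjusted
    change regression (10-year associations), calls tentative signals with
    Benjamini-Hochberg false-discovery-rate control, and prioritizes
    modifiable exposures by cross-trait variance-explained ranking and
    correlation clustering. Includes a synthetic-cohort generator with
    planted effects so every stage is testable without access to cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ape,
    yaml,
    ggplot2,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
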