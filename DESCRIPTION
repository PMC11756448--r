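Package: dilirisk
Title: Donor-Dependent Prediction of Drug-Induced Liver Injury Risk from
    Spheroid Viability Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for donor-dependent in vitro hepatotoxicity
    screens. Fits constrained inhibitory Hill dose-response curves (top = 100,
    bottom = 0) to per-donor, per-drug cell viability data measured over a
    Cmax-multiple concentration series, derives the margin of safety at 20
    percent cell death (MOS20), a toxicity score and severity grade per donor,
    and calls drug-level DILI risk with a cohort-fraction decision rule.
    Includes ROC-based cut-point calibration with Youden's J, confusion-matrix
    performance against clinical DILI labels, binomial cohort-size planning,
    sex- and age-association effect sizes (partial eta-squared, regression
    R-squared), and a synthetic donor-cohort generator with lognormal
    inter-donor IC50 variability, intrinsic and idiosyncratic (plateauing)
    toxicity archetypes, covariate effects and plate noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
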