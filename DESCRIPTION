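Package: hipecpk
Title: Tissue Pharmacokinetics of Intraperitoneal Cisplatin from Microdialysis Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of microdialysis-based tissue
    pharmacokinetic experiments for hyperthermic intraperitoneal
    chemotherapy (HIPEC). Implements retrodialysis-by-drug recovery
    calibration, a closed-form two-compartment kinetic model with
    zero-order drug input and first-order elimination, per-tissue
    nonlinear mixed-effects estimation with animal-level random effects,
    derived pharmacokinetic parameters (AUC, Cmax, Tmax, half-life),
    between-tissue median-ratio comparisons, duplicate-catheter limits of
    agreement on the log scale, and a synthetic-data generator that
    emulates a porcine HIPEC experiment with censoring below the limit of
    quantification and catheter dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    pracma,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    nlme,
    withr
Config/testthat/edition: 3
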