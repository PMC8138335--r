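Package: datsbr
Title: Simulation and Reliability Analysis of Simplified Dopamine
    Transporter PET Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating simplified quantification of striatal
    dopamine transporter (DAT) availability from dynamic PET
    time-activity curves (TACs). Simulates cohorts of subject TACs with
    known ground-truth kinetics from a parametric plasma input and
    compartment models, estimates binding potential (BP_ND) with a
    basis-function implementation of the simplified reference tissue
    model (SRTM), computes specific binding ratios (SBR) over early-peak
    and late pseudo-equilibrium static windows, and derives the full set
    of agreement, discrimination, test-retest and longitudinal change
    statistics (bias, COV, Cohen's d, ROC AUC, absolute variability,
    one-way random ICC, SEM, annual percentage change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    deSolve
Config/testthat/edition: 3
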