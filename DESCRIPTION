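Package: bonejm
Title: Joint Models for Survival and Bone-Turnover Biomarker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combined analysis of survival outcomes and short,
    irregularly observed bone-turnover biomarker series (such as urinary NTX)
    in bone-metastatic cancer cohorts. Provides a synthetic cohort generator
    with a covariate- and biomarker-dependent hazard, three missing-data
    strategies for the biomarker grid (omission, last observation carried
    forward, and fuzzy short-time-series clustering with the optimal
    completion strategy), linear mixed-effects fits of rational, exponential
    and natural cubic spline mean structures, Kaplan-Meier / log-rank / Cox
    and extended (counting-process) Cox regression, and a shared-parameter
    joint model with a piecewise-constant baseline hazard estimated by
    maximum likelihood with adaptive Gauss-Hermite quadrature.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    survival,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
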