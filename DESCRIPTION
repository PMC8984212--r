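Package: cldagate
Title: Simulation and Pre-Specified Analysis of Three-Arm Randomised
    Trials with Constrained Longitudinal Models and Serial Gatekeeping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing three-arm
    placebo-controlled randomised trials with repeated continuous and
    binary outcomes. Implements stratified permuted-block randomisation,
    a synthetic trial generator with configurable treatment effects and
    missingness mechanisms, constrained longitudinal data analysis (cLDA)
    with a common baseline mean and selectable covariance structures,
    serial Bonferroni gatekeeping with Hochberg key-secondary families
    and smallest-rejecting-alpha adjusted p-values, multiple imputation
    by chained equations in wide format with Rubin's-rules pooling,
    complier-average causal effects, Poisson rate and log-binomial
    safety models, analytic power calculations, and an end-to-end
    operating-characteristics simulation harness (type-I error, power,
    bias, coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
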