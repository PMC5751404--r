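Package: biofilmkin
Title: Growth and Kill Kinetics of Bacterial Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic models for bacterial biofilm growth (exponential,
    logistic, Gompertz, von Bertalanffy) and their interaction with
    antimicrobial or growth-promoting agents (linear, threshold and
    saturating effect models for one agent; additive, interaction and
    competitive models for two agents), driven by bolus, infusion or
    interpolated concentration-time profiles.  Includes joint live/dead
    biofilm dynamics, post-plateau decline via an endogenous depletion or
    turnover variable, dormancy lags, biofilm-dependent inhibitory
    concentrations and doubling times.  A statistical layer fits these
    models to confocal-quantification time series by maximum likelihood,
    two-stage population analysis and Laplace-approximate nonlinear
    mixed-effects estimation, with AIC and Hannan-Quinn model selection,
    weighted residuals and empirical-Bayes individual predictions, plus a
    synthetic-data generator emulating multi-channel flow-cell designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
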