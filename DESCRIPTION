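Package: casacomp
Title: Bayesian and Agreement-Based Comparison of Sperm Concentration
    and Motility Measurement Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing measurement methods of boar sperm
    concentration and motility (photometer and computer-assisted sperm
    analysis systems). Fits a Bayesian normal linear mixed model by Gibbs
    sampling under bounded uniform priors, with sire line, month and
    inter-collection interval as fixed effects and a boar-level random
    intercept, and summarises marginal posteriors with relevance-based
    statistics: posterior mean differences, highest-posterior-density
    intervals, probabilities of difference, relevance and similitude, and
    guaranteed values. Companion frequentist agreement statistics include
    Bland-Altman limits of agreement, Passing-Bablok regression, ordinary
    least squares, paired t-tests and one-way ANOVA with Fisher's LSD.
    A synthetic-data generator reproduces the study design (two sire
    lines, ten boars, six months, four devices) with known ground truth
    so the whole pipeline is testable without the original ejaculate
    records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
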