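Package: pedpurge
Title: Pedigree-Based Inbreeding Depression and Purging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying inbreeding depression and its purging in
    closed, pedigreed populations with a binomial survival trait. Implements
    stochastic gene dropping to estimate classical (F), new (Fnew), Kalinowski
    ancestral (Fak) and Ballou ancestral (Fab) inbreeding coefficients with an
    exact enumeration oracle for small pedigrees; deterministic pedigree
    statistics (Meuwissen-Luo inbreeding, additive relationship matrices,
    complete generation equivalents, founder contributions, effective
    population size); binomial logit mixed models with a pedigree-structured
    polygenic random effect; AICc-based multi-model selection, Akaike weights
    and natural-average model averaging; and a synthetic-data generator that
    emulates a closed selected population with overlapping generations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
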