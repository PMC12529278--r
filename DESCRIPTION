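Package: pregreport
Title: Misreporting-Adjusted Analysis of Self-Reported Pregnancy Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing self-reported pregnancy histories subject to
    underreporting. Implements a binomially-thinned zero-inflated Poisson
    model that jointly estimates event rates and reporting probabilities from
    reported counts and exposure times, with maximum-likelihood fitting,
    delta-method standard errors for average reporting rates, and AIC/BIC
    model selection across candidate specifications. Provides the
    reporting-rate correction of outcome prevalence tables, a Bayesian
    multilevel multinomial logistic regression of pregnancy outcome with
    woman-level random intercepts (adaptive Metropolis-within-Gibbs sampler),
    and a synthetic survey-data generator emulating the structure of a
    retrospective reproductive-health survey so the whole pipeline is testable
    without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), nnet, withr
Config/testthat/edition: 3
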