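# pregreport

Misreporting-adjusted analysis of self-reported pregnancy histories.

Population surveys are the only nationally representative source on
miscarriage and abortion, but respondents underreport both: some report zero
events despite having experienced them, others report fewer than occurred.
`pregreport` is for epidemiologists and demographers who want to (i) estimate
*how completely* such events are reported, (ii) correct prevalence tables for
the estimated reporting rates, and (iii) model pregnancy-outcome risk with
woman-level unobserved heterogeneity — all on ordinary respondent- and
pregnancy-level tables, with a synthetic-data generator that makes every step
testable without access to restricted survey microdata.

## The models

**Reported counts.** True event counts follow a zero-inflated Poisson with
exposure offset,

    P(Y* = 0)        = phi + (1 - phi) exp(-lambda t)
    P(Y* = y | y>0)  = (1 - phi) (lambda t)^y exp(-lambda t) / y!

with `lambda = exp(beta'X)` and `phi = plogis(delta'Z)`. Each true event is
reported independently with probability `pi = plogis(gamma'W)` (binomial
thinning, `Y = pi o Y*`), so the observed count is again zero-inflated
Poisson with rate `pi * lambda`. Maximum-likelihood fitting, per-respondent
predicted reporting rates, delta-method standard errors for average rates,
and AIC/BIC selection across candidate specifications are provided. Because
`pi` and `lambda` are separated only by exclusion restrictions and link
curvature, specifications without an exclusion restriction are flagged with a
formal identification warning.

**Prevalence correction.** Reported outcome shares are divided by
outcome-specific reporting rates and renormalised:
`corrected_k = (reported_k / rate_k) / sum_j (reported_j / rate_j) * 100`.

**Outcome risk.** A Bayesian multilevel multinomial logistic regression of
pregnancy outcome (live birth / miscarriage / abortion, live birth as
reference) with per-outcome woman-level random intercepts
`u_ik ~ N(0, sigma_k^2)`, sampled by the package's adaptive
Metropolis-within-Gibbs algorithm, with split-Rhat/ESS diagnostics and
marginally standardised predicted probabilities.

## Worked example

```r
library(pregreport)

# synthetic survey emulating a 25-49 female respondent panel
cfg  <- fecond_like_preset(n_women = 2000, seed = 42)
resp <- simulate_respondents(cfg)

# reporting model: parity identifies the count equation, income/health/
# marital status identify the reporting equation
spec <- btzip_spec(
  count_covariates  = c("education", "parity_survey"),
  zero_covariates   = "infertility_treatment",
  report_covariates = c("education", "income", "health", "marital"))
fit <- btzip_fit(resp, spec)
average_reporting_rate(fit, resp, by = "education")
#> Estimated reporting rates (%)
#>        subgroup  rate   se    n
#>         Average  92.7 3.18 2000
#>  below_tertiary  90.0 4.38 1455
#>        tertiary 100.0 0.38  545
```

On these simulated data (generator truth: 92.4% average reporting with a
strong education gradient) the model recovers a 92.7% average reporting rate,
with tertiary-educated respondents reporting essentially everything.

```r
# correct a reported outcome distribution for underreporting
reported <- outcome_distribution(c(miscarriage = 13.9, abortion = 10.3,
                                   live_birth = 72.8, other = 3.0))
correct_distribution(reported, c(miscarriage = 92, abortion = 55))
#> Pregnancy outcome distribution (%)
#> miscarriage    abortion  live_birth       other
#>        13.8        17.1        66.4         2.7
```

Dividing each share by its reporting rate and renormalising leaves the
miscarriage share nearly unchanged (13.9 -> 13.8) while the abortion share,
reported at only 55%, rises from 10.3 to 17.1.

The risk model and the full pipeline run the same way:

```r
preg <- simulate_pregnancies(cfg)
sp   <- mnl_spec(c("age_group_at_start", "prior_miscarriages", "education"),
                 chains = 4, iter = 6000, seed = 1)
rfit <- fit_risk_model(preg, sp)          # posterior summary in rfit$summary
predict_probabilities(rfit, "age_group_at_start")

run_pipeline(pipeline_config(out_dir = "run1", seed = 42))
```

A thin command-line front-end over the same functions ships in
`inst/cli/pregreport.R` (subcommands `simulate`, `fit-reporting`,
`select-model`, `correct`, `fit-risk`, `run-all`).

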