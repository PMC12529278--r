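---
title: "Misreporting-adjusted analysis of self-reported pregnancy histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misreporting-adjusted analysis of self-reported pregnancy histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregreport)
```

## The problem

Retrospective surveys ask women how many times they have been pregnant and how
each pregnancy ended. Two distortions stand between those answers and the true
event history. Some respondents report *zero* events of a kind (miscarriage,
abortion) despite having experienced them — excess zeros beyond what exposure
alone would predict. Others report a positive count that is *lower* than the
truth. Both distortions bias prevalence estimates and can masquerade as social
gradients in risk when reporting itself is socially patterned.

`pregreport` implements the two-part analysis this situation calls for: first
estimate how completely events are reported and correct prevalence shares;
then, having established the scale of the problem, model outcome risk at the
pregnancy level with woman-level unobserved heterogeneity.

## The reported-count model

Let $Y^*_i$ be the true number of events woman $i$ experienced over her
exposure time $t_i$ (years since the earlier of menarche and first
intercourse). The true count follows a zero-inflated Poisson:

$$P(Y^* = 0) = \varphi + (1-\varphi) e^{-\lambda t}, \qquad
  P(Y^* = y \mid y > 0) = (1-\varphi) \frac{(\lambda t)^y e^{-\lambda t}}{y!},$$

with a log-linear event rate $\lambda_i = \exp(\beta' X_i)$ and a logistic
zero-inflation probability $\varphi_i = \operatorname{logit}^{-1}(\delta'
Z_i)$. Each true event is then *reported* independently with probability
$\pi_i = \operatorname{logit}^{-1}(\gamma' W_i)$, so the observed count is the
binomial thinning $Y = \pi \circ Y^*$. A convenient closed form makes the
likelihood exact: the thinned count is again zero-inflated Poisson with rate
$\pi\lambda$ and unchanged $\varphi$. The package evaluates that closed form
(`observed_logpmf()`); the explicit ZIP-times-binomial convolution is retained
in the test suite as an independent oracle.

Parameters are estimated by maximum likelihood (`btzip_fit()`), the average
reporting rate is the arithmetic mean of the per-respondent
$\hat\pi_i$ (`average_reporting_rate()`), and its standard error comes from
the delta method through the full coefficient covariance.

### Identification, and why the optimizer is built the way it is

The observed data alone follow ZIP$(\pi\lambda t, \varphi)$, so $\pi$ and
$\lambda$ are separated only by *exclusion restrictions* (covariates entering
one equation but not the other) and by the curvature of the logistic link.
When $\pi$ is small the logistic is nearly exponential and $\pi\lambda$
collapses into a single log-linear ridge; the likelihood then has two basins —
a saturated-reporting mode and a near-exponential small-$\pi$ ridge. The
fitted surface is genuinely bimodal at moderate sample sizes, and which basin
carries the global maximum depends on the data realisation: in our
simulations with survey-like event rates the degenerate basin ties or beats
the saturated mode on some realisations even at $n = 20{,}000$, while on
others the saturated mode wins comfortably. The maximum-likelihood *value* is
nearly indifferent along these ridges while the implied average reporting
rate swings widely — so a single fit's point estimate should never be read
without the robustness sweep across specifications.

`btzip_fit()` therefore starts BFGS from deterministic anchors at reporting
intercepts $\operatorname{logit}^{-1}$-equal to 0.5, 0.9 and 0.99 (count
intercept matched so $\pi\lambda$ reproduces the observed mean count), plus
seeded random perturbations, and keeps the best optimum. A specification
whose count and reporting equations share the same covariate set is flagged
with a formal identification warning at construction time, and the test suite
verifies that the profile likelihood along $\pi\lambda = \text{const}$ is
flat in that case.

Two consequences are worth knowing. Near the boundary ($\pi \to 1$) the
profile is flat within a percentage point or two, so a reporting rate of
100% in truth is recovered as 98-odd percent, not as exactly 100. And the
coefficient covariance is obtained from an eigendecomposition pseudo-inverse
of the observed information, so saturated directions get zero
inverse-information instead of destroying the whole matrix. Delta-method
standard errors are trustworthy in identified regimes — the suite checks them
against a 300-replicate parametric bootstrap in a design with a saturated
reporting subgroup — but in weakly identified designs the sampling
distribution of the MLE is bimodal and *no* curvature-based standard error
describes it; the robustness sweep across specifications
(`robustness_table()`), not the standard error, is the honest uncertainty
statement there.

Survey weights are deliberately not used in the likelihood: fits are
unweighted maximum likelihood, and weights are honoured only in descriptive
tabulations (`tabulate_outcomes(weight = )`).

## Correcting an outcome distribution

`correct_distribution()` divides each reported share by its outcome-specific
reporting rate (in percent) and renormalises to 100. Outcomes without a
supplied rate are assumed fully reported. Rounding to one decimal happens only
at display; internally full precision is kept, the corrected shares sum to
exactly 100, and "uncorrecting" with the same rates recovers the input to
machine precision.

```{r correction}
reported <- outcome_distribution(c(miscarriage = 13.9, abortion = 10.3,
                                   live_birth = 72.8, other = 3.0))
correct_distribution(reported, c(miscarriage = 92, abortion = 55))
```

## The pregnancy-outcome risk model

At the pregnancy level the outcome $Y_{ij}$ of pregnancy $j$ of woman $i$
takes one of three values with live birth as the reference:

$$P(Y_{ij} = k) = \frac{e^{\eta_{ijk}}}{1 + e^{\eta_{ij1}} + e^{\eta_{ij2}}},
\qquad \eta_{ijk} = \beta_{0k} + \beta_k' X_{ij} + u_{ik},$$

with woman-level random intercepts $u_{ik} \sim N(0, \sigma_{u,k}^2)$. We
give each non-reference outcome its own $\sigma_{u,k}$ with independent
intercepts — the shared-variance model is a recoverable special case, and the
more general form costs little. Priors are weakly informative and concrete:
$N(0, 5^2)$ on fixed effects and half-Student-$t(3, 2.5)$ on the
random-intercept SDs.

Sampling is by an adaptive Metropolis-within-Gibbs algorithm owned by the
package: per-outcome fixed-effect blocks use a random-walk proposal whose
covariance is re-estimated from the warmup history (scale reset to
$2.38/\sqrt{p}$ at each re-estimation), woman-level intercepts are updated
jointly with per-woman accept/reject decisions, and each $\sigma_{u,k}$ gets
both a centered log-scale step and a non-centered interweaving step that
rescales all of that outcome's intercepts at once — without the interweaving
step the $u$–$\sigma$ funnel mixes an order of magnitude more slowly. All
adaptation freezes at the end of warmup, defaults are 4 chains of 6000
iterations with the first half as warmup, and identical seed, spec and data
reproduce the draws exactly. Split-$\hat R$ and effective sample sizes are
computed for every reported parameter; a fit with $\hat R > 1.05$ or ESS
below 100 is returned with a prominent warning, never silently.

With `include_random_effects = FALSE` the same machinery runs with $u \equiv
0$, and a maximum-a-posteriori estimate by direct optimisation is stored
alongside — the test suite checks it against an independently coded optimiser
to $10^{-4}$ and uses it as a concentration check on the posterior means.

Predicted probabilities (`predict_probabilities()`) use marginal
standardisation: for each posterior draw the focal covariate is set to a
chosen level in every observed row and probabilities are averaged over rows
and over 200 fresh Monte Carlo draws of the random intercepts; the 95%
interval is the 2.5/97.5 percentile of the draw-level averages.

## What the synthetic generator emulates — and what it does not

`simulate_respondents()` and `simulate_pregnancies()` generate data with
exactly the statistical structure the two models assume: covariate-dependent
ZIP counts binomially thinned by a covariate-dependent reporting probability;
exposure from discrete menarche / first-intercourse / interview age
distributions; and per-woman outcome sequences from the random-intercept
multinomial logit, with `prior_miscarriages` and `parity_at_start` updated
between pregnancies from the simulated history itself. A `frailty_sd`
option adds a shared woman-level term to both the expected number of
pregnancies and the miscarriage predictor, coupling history length to risk —
the scenario in which a pooled model shows a spurious positive
prior-miscarriage effect that the random-intercept model absorbs.

`fecond_like_preset()` fixes the generator at survey-like values: an average
miscarriage reporting probability near 92% with a strong education gradient,
a miscarriage share near 14% of pregnancies, elevated risk at advanced
maternal age, and category frequencies loosely matching published survey
marginals. Where the source survey's design is not published as a
distribution (exposure-age distributions, pregnancy spacing), the preset uses
plausible stand-ins: menarche on 11–16, first intercourse on 15–25, interview
ages uniform on 25–49, first pregnancy around age 25, about two pregnancies
per woman. Covariates are drawn independently — only marginal frequencies are
emulated, not the real survey's correlation structure, its sampling design,
or its non-response weighting. Passing tests therefore certify the
*estimators* under the assumed data-generating process, not the models'
adequacy for any particular real survey.

## Numerical and design choices

* **Category encoding.** Categorical covariates are one-hot encoded against
  the first level after a locale-independent radix sort, so refits are
  invariant to row order and platform locale.
* **Complete cases.** Rows with nonpositive exposure or missing analysis
  variables are dropped with a logged count before fitting; in model
  selection the complete-case rows are fixed once over the *union* of all
  candidates' covariates so AIC/BIC are comparable across candidates. Ties in
  the ranking break lexicographically by label.
* **Display convention.** Reporting rates print with one decimal and
  saturate at 100.0.
* **Problem sizes in the test suite.** Generator calibration and moment
  identities are checked at $n = 10^5$; reporting-rate recovery and nested
  model selection at $n = 8{,}000$ respondents; the bootstrap-vs-delta
  standard-error comparison uses 300 replicates at $n = 1{,}500$; MCMC
  recovery and the frailty contrast run 2 chains of 2000–4000 iterations on
  800–1200 women. These sizes were chosen so each check has clear resolving
  power for the property it asserts.
* **Seeding.** Every simulator and sampler takes an explicit integer seed and
  restores the caller's RNG state. The pipeline fans one global seed out to
  stages as `seed + 1000 * stage_index`.

## Known limitations

The reporting model offers no negative-binomial or overreporting variants,
and corrected prevalence shares carry no propagated uncertainty from the
estimated reporting rates — they are point corrections. The risk model
supports exactly three outcome categories (two non-reference), categorical
covariates only, and fits unweighted. In weakly identified reporting-model
designs the MLE's sampling distribution is bimodal and results should be read
through the robustness sweep rather than any single fit.
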