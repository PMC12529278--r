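small_spec <- function() {
  btzip_spec(count_covariates = "education",
             zero_covariates = "infertility_treatment",
             report_covariates = c("income", "health"))
}

test_that("candidate sets enforce unique labels and valid specs", {
  expect_error(candidate_set(a = small_spec(), a = small_spec()), "unique")
  expect_error(candidate_set(a = "not a spec"), "btzip_spec")
})

test_that("candidates are fitted on a shared complete-case sample", {
  r <- simulate_respondents(fecond_like_preset(n_women = 600, seed = 23))
  r$income[1:10] <- NA  # missing only for one candidate's covariate
  cands <- candidate_set(with_income = small_spec(),
                         no_income = btzip_spec(
                           count_covariates = "education",
                           zero_covariates = "infertility_treatment",
                           report_covariates = "health"))
  fits <- fit_candidates(r, cands, control = list(n_starts = 2))
  # both candidates were fitted on the same (complete-case) rows
  expect_equal(fits$with_income$n_obs, 590)
  expect_equal(fits$no_income$n_obs, 590)
})

test_that("a candidate referencing absent columns is skipped, others proceed", {
  r <- simulate_respondents(fecond_like_preset(n_women = 400, seed = 3))
  cands <- candidate_set(
    ok = small_spec(),
    ghost = btzip_spec(count_covariates = "no_such_column",
                       report_covariates = "health"))
  fits <- fit_candidates(r, cands, control = list(n_starts = 2))
  expect_null(fits$ghost)
  expect_s3_class(fits$ok, "btzip_fit")
  tab <- robustness_table(fits, r)
  expect_equal(nrow(tab), 1)
  expect_true(tab$best_aic && tab$best_bic)
})

test_that("a degenerate constant covariate is recorded as non-converged", {
  r <- simulate_respondents(fecond_like_preset(n_women = 400, seed = 9))
  r$constant <- "same"
  cands <- candidate_set(
    ok = small_spec(),
    flat = btzip_spec(count_covariates = "constant",
                      report_covariates = "health"))
  fits <- fit_candidates(r, cands, control = list(n_starts = 2))
  expect_false(is.null(fits$flat) && is.null(fits$ok))
  tab <- robustness_table(fits, r)
  expect_false(tab$converged[tab$label == "flat"])
  expect_true(tab$converged[tab$label == "ok"])
})

test_that("average rates are stable across correctly specified candidates", {
  cfg <- sim_config(
    n_women = 2000, seed = 52,
    covariate_marginals = list(
      parity = c(`0` = 0.4, `1` = 0.3, `2+` = 0.3),
      edu = c(low = 0.6, high = 0.4),
      health = c(good = 0.8, not_good = 0.2),
      region = c(north = 0.5, south = 0.5)),
    beta_count = c("(Intercept)" = log(0.05), "parity:1" = 0.4,
                   "parity:2+" = 0.7),
    delta_zero = c("(Intercept)" = qlogis(0.2)),
    gamma_report = c("(Intercept)" = 1.2, "edu:high" = 4.0,
                     "health:not_good" = 1.0),
    ages = list(menarche = c(`14` = 1), first_sex = c(`18` = 1),
                interview = c(`40` = 1)))
  r <- simulate_respondents(cfg)
  cands <- candidate_set(
    full = btzip_spec("parity", character(), c("edu", "health")),
    with_region = btzip_spec(c("parity", "region"), character(),
                             c("edu", "health")),
    zero_region = btzip_spec("parity", "region", c("edu", "health")),
    lean = btzip_spec(character(), character(), c("edu", "health")),
    no_edu = btzip_spec("parity", character(), "health"))
  fits <- fit_candidates(r, cands)
  tab <- robustness_table(fits, r)
  expect_true(all(tab$converged))

  # candidates sharing the true reporting covariates agree closely
  shared <- tab[tab$label != "no_edu", ]
  expect_lt(max(shared$avg_reporting_rate) - min(shared$avg_reporting_rate), 10)
  # dropping the key reporting covariate moves the estimate the most
  full_rate <- tab$avg_reporting_rate[tab$label == "full"]
  devs <- abs(tab$avg_reporting_rate - full_rate)
  expect_equal(tab$label[which.max(devs)], "no_edu")
})

test_that("information criteria in the table reproduce from stored fits", {
  r <- simulate_respondents(fecond_like_preset(n_women = 500, seed = 15))
  cands <- candidate_set(a = small_spec(), b = preset_spec())
  fits <- fit_candidates(r, cands, control = list(n_starts = 2))
  tab <- robustness_table(fits, r)
  for (lab in tab$label) {
    fit <- fits[[lab]]
    p <- length(c(fit$beta, fit$delta, fit$gamma))
    expect_equal(tab$aic[tab$label == lab], -2 * fit$loglik + 2 * p,
                 tolerance = 1e-10)
    expect_equal(tab$bic[tab$label == lab],
                 -2 * fit$loglik + p * log(fit$n_obs), tolerance = 1e-10)
  }
  expect_equal(sum(tab$best_aic), 1)
  expect_equal(sum(tab$best_bic), 1)
})
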