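test_that("total log-likelihood reduces to the single-row pmf and is additive", {
  one <- data.frame(woman_id = 1, y_reported = 0, t_exposure = 1,
                    weight = 1)
  sp <- suppressWarnings(btzip_spec())  # intercept-only everywhere
  params <- list(beta = c("(Intercept)" = 0),
                 delta = c("(Intercept)" = qlogis(0.3)),
                 gamma = c("(Intercept)" = qlogis(0.5)))
  expect_equal(btzip_loglik(one, sp, params),
               observed_logpmf(0, 1, 0.3, 0.5))

  r <- simulate_respondents(fecond_like_preset(n_women = 40, seed = 8))
  spec <- preset_spec()
  p2 <- list(
    beta = c("(Intercept)" = -3, "education:tertiary" = 0.2,
             "parity_survey:1" = 0.1, "parity_survey:2+" = 0.3),
    delta = c("(Intercept)" = -1, "infertility_treatment:yes" = -0.5),
    gamma = c("(Intercept)" = 1.5, "education:tertiary" = 1,
              "income:2500_3499" = -0.2, "income:3500+" = 0.4,
              "income:<1500" = 0.1, "health:not_good" = 0.3,
              "marital:not_married" = 0.2))
  ll <- btzip_loglik(r, spec, p2)
  doubled <- rbind(r, r)
  expect_equal(btzip_loglik(doubled, spec, p2), 2 * ll, tolerance = 1e-12)
})

test_that("total log-likelihood matches the row-by-row convolution oracle", {
  set.seed(3)
  n <- 50
  dat <- data.frame(
    woman_id = 1:n,
    y_reported = rpois(n, 1),
    t_exposure = runif(n, 5, 30),
    weight = 1,
    grp = sample(c("a", "b"), n, replace = TRUE)
  )
  sp <- btzip_spec(count_covariates = "grp")
  params <- list(beta = c("(Intercept)" = -2.4, "grp:b" = 0.4),
                 delta = c("(Intercept)" = -0.8),
                 gamma = c("(Intercept)" = 1.2))
  lambda <- exp(-2.4 + 0.4 * (dat$grp == "b"))
  phi <- plogis(-0.8)
  pi <- plogis(1.2)
  oracle <- sum(vapply(seq_len(n), function(i)
    conv_obs_logpmf(dat$y_reported[i], lambda[i] * dat$t_exposure[i], phi, pi),
    numeric(1)))
  expect_equal(btzip_loglik(dat, sp, params), oracle, tolerance = 1e-10)
})

test_that("likelihood is invariant to row order and fit is reproducible", {
  r <- simulate_respondents(fecond_like_preset(n_women = 1200, seed = 21))
  spec <- preset_spec()
  fit1 <- btzip_fit(r, spec, control = list(n_starts = 2))
  perm <- r[sample(nrow(r)), ]
  fit2 <- btzip_fit(perm, spec, control = list(n_starts = 2))
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)
  expect_equal(fit2$gamma, fit1$gamma, tolerance = 1e-6)
})

test_that("with thinning off the fitted reporting rate sits near the boundary", {
  cfg <- fecond_like_preset(n_women = 5000, seed = 21)
  cfg$gamma_report <- c("(Intercept)" = 20)  # pi = 1 in truth
  r <- simulate_respondents(cfg)
  fit <- btzip_fit(r, preset_spec(), control = list(n_starts = 3))
  tab <- average_reporting_rate(fit, r)
  # the profile along pi*lambda is flat within ~2pp of the boundary, so the
  # MLE is pinned near, not at, 100%
  expect_gte(tab$rate[1], 97)
})

test_that("stored AIC/BIC reproduce from loglik and parameter count", {
  r <- simulate_respondents(fecond_like_preset(n_women = 800, seed = 13))
  fit <- btzip_fit(r, preset_spec(), control = list(n_starts = 2))
  p <- length(c(fit$beta, fit$delta, fit$gamma))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * p, tolerance = 1e-10)
  expect_equal(fit$bic, -2 * fit$loglik + p * log(fit$n_obs), tolerance = 1e-10)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_equal(fit$vcov, t(fit$vcov))
})

test_that("predicted rates follow the logistic link", {
  r <- simulate_respondents(fecond_like_preset(n_women = 400, seed = 2))
  fit <- btzip_fit(r, preset_spec(), control = list(n_starts = 2))

  # hand-crafted coefficient values make the predictions checkable
  fit$gamma[] <- 0
  pr <- predict_rates(fit, r)
  expect_equal(pr$pi, rep(0.5, nrow(r)))
  expect_true(all(pr$lambda > 0))
  expect_true(all(pr$phi > 0 & pr$phi < 1))

  fit$gamma["(Intercept)"] <- 20
  pr2 <- predict_rates(fit, r)
  expect_true(all(pr2$pi > 0.999999))
  expect_identical(pregreport:::format_rate(100 * pr2$pi[1]), "100.0")

  # monotonicity: a positive coefficient raises pi for that category
  fit$gamma[] <- 0
  fit$gamma["health:not_good"] <- 1.3
  pr3 <- predict_rates(fit, r)
  expect_true(all(pr3$pi[r$health == "not_good"] >
                    pr3$pi[r$health == "good"][1]))

  bad <- r[1:3, ]
  bad$income <- "unheard_of"
  expect_error(predict_rates(fit, bad), "unheard_of")
})

test_that("average reporting rate is the arithmetic mean of predictions", {
  r <- simulate_respondents(fecond_like_preset(n_women = 300, seed = 6))
  fit <- btzip_fit(r, preset_spec(), control = list(n_starts = 2))
  pr <- predict_rates(fit, r)
  tab <- average_reporting_rate(fit, r, by = "education")
  expect_equal(tab$rate[tab$subgroup == "Average"], 100 * mean(pr$pi),
               tolerance = 1e-10)
  # the average row is the observation-weighted mean of subgroup rows
  sub <- tab[tab$subgroup != "Average", ]
  expect_equal(sum(sub$rate * sub$n) / sum(sub$n),
               tab$rate[tab$subgroup == "Average"], tolerance = 1e-8)
  expect_true(all(tab$rate >= 0 & tab$rate <= 100))
})

test_that("delta-method SE agrees with a parametric bootstrap", {
  # a design where the reporting probability is crisply identified: one
  # subgroup's reporting saturates near 1, anchoring the event rate
  cfg <- sim_config(
    n_women = 1500, seed = 31,
    covariate_marginals = list(
      parity = c(`0` = 0.4, `1` = 0.3, `2+` = 0.3),
      edu = c(low = 0.6, high = 0.4),
      health = c(good = 0.8, not_good = 0.2)),
    beta_count = c("(Intercept)" = log(0.05), "parity:1" = 0.4,
                   "parity:2+" = 0.7),
    delta_zero = c("(Intercept)" = qlogis(0.2)),
    gamma_report = c("(Intercept)" = 1.2, "edu:high" = 4.0,
                     "health:not_good" = 1.0),
    ages = list(menarche = c(`14` = 1), first_sex = c(`18` = 1),
                interview = c(`40` = 1)))
  r <- simulate_respondents(cfg)
  sp <- btzip_spec(count_covariates = "parity",
                   report_covariates = c("edu", "health"))
  fit <- btzip_fit(r, sp, control = list(n_starts = 3))
  tab <- average_reporting_rate(fit, r)

  pr <- predict_rates(fit, r)
  warm <- c(fit$beta, fit$delta, fit$gamma)
  set.seed(77)
  boot <- replicate(300, {
    y_true <- ifelse(runif(nrow(r)) < pr$phi, 0L,
                     rpois(nrow(r), pr$lambda * r$t_exposure))
    rb <- r
    rb$y_reported <- rbinom(nrow(r), y_true, pr$pi)
    fb <- suppressWarnings(
      btzip_fit(rb, sp, control = list(n_starts = 1, start = warm)))
    if (fb$converged) average_reporting_rate(fb, rb)$rate[1] else NA_real_
  })
  boot_se <- sd(boot, na.rm = TRUE)
  expect_lt(abs(tab$se[1] - boot_se) / boot_se, 0.25)
})

test_that("rows with nonpositive exposure or missing covariates are dropped with a count", {
  r <- simulate_respondents(fecond_like_preset(n_women = 200, seed = 4))
  r$t_exposure[1:5] <- 0
  r$income[6:8] <- NA
  expect_message(fit <- btzip_fit(r, preset_spec(), control = list(n_starts = 1)),
                 "dropped 8 of 200")
  expect_equal(fit$n_obs, 192)
  expect_equal(fit$n_dropped, 8)
})
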