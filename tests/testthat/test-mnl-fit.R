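# A compact generator for risk-model tests: coefficients are expressed
# against the radix-sorted reference levels the fitter uses, so generator
# truth and fitted contrasts are directly comparable.
risk_test_config <- function(n_women, seed, re_sd = c(miscarriage = 0, abortion = 0),
                             frailty_sd = 0) {
  cfg <- fecond_like_preset(n_women = n_women, seed = seed)
  cfg$outcome_coefs <- list(
    miscarriage = c("(Intercept)" = -1.6,
                    "relationship:unstable" = 0.4,
                    "work_issues:yes" = -0.7),
    abortion = c("(Intercept)" = -1.9,
                 "relationship:unstable" = 0.9))
  cfg$re_sd <- re_sd
  cfg$frailty_sd <- frailty_sd
  cfg
}

test_that("spec validation catches malformed requests", {
  expect_error(mnl_spec("x", outcomes = "only_one"), "exactly two")
  expect_error(mnl_spec("x", reference = "miscarriage"), "reference")
  expect_error(mnl_spec("x", chains = 1), "chains")
  expect_error(mnl_spec("x", iter = 100, warmup = 100), "exceed")
})

test_that("degenerate single-outcome data fail with the outcome named", {
  preg <- data.frame(woman_id = 1:20, pregnancy_index = 1,
                     outcome = "live_birth",
                     relationship = sample(c("stable", "unstable"), 20, TRUE))
  sp <- mnl_spec("relationship", chains = 2, iter = 200, warmup = 100)
  expect_error(fit_risk_model(preg, sp), "live_birth")
})

test_that("the no-RE MAP agrees with an independent direct maximisation", {
  preg <- simulate_pregnancies(risk_test_config(320, seed = 9))
  expect_gt(nrow(preg), 400)
  sp <- mnl_spec(c("relationship", "work_issues"),
                 include_random_effects = FALSE,
                 chains = 2, iter = 400, warmup = 200, seed = 2)
  fit <- suppressWarnings(fit_risk_model(preg, sp))

  # independent oracle: nlm on an independently coded log posterior over a
  # model.matrix design
  dat <- fit$data
  f_rel <- factor(dat$relationship, levels = sort(unique(dat$relationship)))
  f_work <- factor(dat$work_issues, levels = sort(unique(dat$work_issues)))
  X <- model.matrix(~ f_rel + f_work)
  y <- dat$outcome
  negpost <- function(th) {
    b1 <- th[1:ncol(X)]; b2 <- th[(ncol(X) + 1):(2 * ncol(X))]
    e1 <- drop(X %*% b1); e2 <- drop(X %*% b2)
    denom <- log(1 + exp(e1) + exp(e2))
    lp <- ifelse(y == "miscarriage", e1, ifelse(y == "abortion", e2, 0))
    -(sum(lp - denom) + sum(dnorm(th, 0, 5, log = TRUE)))
  }
  opt <- nlm(negpost, rep(0, 2 * ncol(X)), gradtol = 1e-12, iterlim = 500)
  oracle <- matrix(opt$estimate, ncol = 2)
  expect_equal(unname(fit$map), unname(oracle), tolerance = 1e-4)
})

test_that("MAP approaches plain maximum likelihood under a flat prior", {
  skip_if_not_installed("nnet")
  preg <- simulate_pregnancies(risk_test_config(300, seed = 12))
  sp <- mnl_spec("relationship", include_random_effects = FALSE,
                 chains = 2, iter = 400, warmup = 200,
                 prior = list(beta_sd = 1000))
  fit <- suppressWarnings(fit_risk_model(preg, sp))
  dat <- fit$data
  dat$outcome <- factor(dat$outcome,
                        levels = c("live_birth", "miscarriage", "abortion"))
  ml <- nnet::multinom(outcome ~ relationship, data = dat, trace = FALSE,
                       reltol = 1e-12)
  cf <- coef(ml)  # rows: miscarriage, abortion
  expect_equal(unname(fit$map[, "miscarriage"]), unname(cf["miscarriage", ]),
               tolerance = 1e-3)
  expect_equal(unname(fit$map[, "abortion"]), unname(cf["abortion", ]),
               tolerance = 1e-3)
})

test_that("sampling is deterministic given spec and data", {
  preg <- simulate_pregnancies(risk_test_config(120, seed = 3))
  sp <- mnl_spec("relationship", chains = 2, iter = 300, warmup = 150, seed = 11)
  f1 <- suppressWarnings(fit_risk_model(preg, sp))
  f2 <- suppressWarnings(fit_risk_model(preg, sp))
  expect_identical(f1$beta_draws, f2$beta_draws)
  expect_identical(f1$sigma_draws, f2$sigma_draws)
})

test_that("posterior means track the MAP on well-identified no-RE data", {
  preg <- simulate_pregnancies(risk_test_config(700, seed = 14))
  sp <- mnl_spec(c("relationship", "work_issues"),
                 include_random_effects = FALSE,
                 chains = 2, iter = 1200, warmup = 600, seed = 5)
  fit <- suppressWarnings(fit_risk_model(preg, sp))
  post_mean <- sapply(fit$beta_draws, colMeans)
  expect_equal(unname(post_mean), unname(fit$map), tolerance = 0.1)
})

test_that("predicted probabilities reduce to closed forms", {
  preg <- simulate_pregnancies(risk_test_config(150, seed = 8))
  sp <- mnl_spec("relationship", include_random_effects = FALSE,
                 chains = 2, iter = 300, warmup = 150, seed = 4)
  fit <- suppressWarnings(fit_risk_model(preg, sp))

  # all-zero coefficients, no RE: every profile gives (1/3, 1/3, 1/3)
  flat <- fit
  flat$beta_draws <- lapply(flat$beta_draws, function(m) m * 0)
  pp <- predict_probabilities(flat, "relationship")
  expect_equal(pp$mean, rep(1 / 3, nrow(pp)), tolerance = 1e-12)
  expect_equal(pp$upper - pp$lower, rep(0, nrow(pp)), tolerance = 1e-12)

  # single-draw point mass equals outcome_probs of that draw's eta
  point <- fit
  point$beta_draws <- lapply(fit$beta_draws, function(m)
    m[1, , drop = FALSE])
  point$sigma_draws <- fit$sigma_draws[1, , drop = FALSE] * 0
  pp2 <- predict_probabilities(point, "relationship", levels = "unstable")
  X1 <- cbind(1, 1)  # intercept + unstable dummy
  eta1 <- sum(point$beta_draws[[1]][1, ])
  eta2 <- sum(point$beta_draws[[2]][1, ])
  expect_equal(pp2$mean, unname(outcome_probs(eta1, eta2)), tolerance = 1e-12)

  expect_error(predict_probabilities(fit, "relationship", levels = "nope"),
               "unseen")
})
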