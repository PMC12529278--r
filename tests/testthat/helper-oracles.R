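# Independent oracles, written directly from the probability definitions and
# kept free of the package's own pmf/likelihood code paths.

# Observed (thinned) pmf by explicit convolution: sum over true counts of
# ZIP(y*; lt, phi) times Binomial(y | y*, pi), truncated at y* = ymax.
conv_obs_pmf <- function(y, lt, phi, pi, ymax = 500) {
  ystar <- 0:ymax
  p_zip <- (ystar == 0) * phi + (1 - phi) * dpois(ystar, lt)
  sum(p_zip * dbinom(y, ystar, pi))
}

conv_obs_logpmf <- function(y, lt, phi, pi, ymax = 500) {
  log(conv_obs_pmf(y, lt, phi, pi, ymax))
}

# Direct per-row multinomial log-likelihood (naive loop, unnormalised by
# construction impossible: probabilities computed row by row).
naive_mnl_loglik <- function(pregnancies, params, u, reference = "live_birth") {
  ks <- names(params)
  ll <- 0
  for (i in seq_len(nrow(pregnancies))) {
    row <- pregnancies[i, , drop = FALSE]
    eta <- vapply(ks, function(k) {
      e <- params[[k]][["(Intercept)"]]
      for (nm in setdiff(names(params[[k]]), "(Intercept)")) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        cov <- parts[1]; lev <- paste(parts[-1], collapse = ":")
        if (row[[cov]] == lev) e <- e + params[[k]][[nm]]
      }
      e + u[as.character(row$woman_id), k]
    }, numeric(1))
    denom <- 1 + sum(exp(eta))
    out <- as.character(row$outcome)
    p <- if (out == reference) 1 / denom else exp(eta[[out]]) / denom
    ll <- ll + log(p)
  }
  ll
}

# A small constant-rate configuration: degenerate ages give constant
# exposure t = 22 so lambda * t is the same for every woman.
constant_rate_config <- function(n_women, seed, lambda_t = 1, phi = 0.2,
                                 pi = 0.8) {
  sim_config(
    n_women = n_women, seed = seed,
    beta_count = c("(Intercept)" = log(lambda_t / 22)),
    delta_zero = c("(Intercept)" = qlogis(phi)),
    gamma_report = c("(Intercept)" = qlogis(pi)),
    ages = list(menarche = c(`14` = 1), first_sex = c(`18` = 1),
                interview = c(`36` = 1))
  )
}

# Preset-matching BT-ZIP specification (the generator's exclusion
# restrictions: parity in the count equation only, income/health/marital in
# the reporting equation only).
preset_spec <- function() {
  btzip_spec(
    count_covariates = c("education", "parity_survey"),
    zero_covariates = "infertility_treatment",
    report_covariates = c("education", "income", "health", "marital"),
    label = "generator"
  )
}
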