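# Synthetic survey-data generators. Both simulators run under a private RNG
# state seeded from the config, so identical config + seed gives identical
# tables and the caller's RNG stream is untouched.

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_categories <- function(marginal, n) {
  names(marginal)[sample.int(length(marginal), n, replace = TRUE, prob = marginal)]
}

#' Simulate respondent records with misreported event counts
#'
#' Generates one row per woman. Covariates are drawn independently from the
#' configured marginals; exposure time is interview age minus the earlier of
#' menarche and first-intercourse age. The true event count is zero with
#' probability `phi_i = plogis(delta'Z_i)` and otherwise Poisson with mean
#' `lambda_i * t_i`, `lambda_i = exp(beta'X_i)`; the reported count thins the
#' true count binomially with per-woman reporting probability
#' `pi_i = plogis(gamma'W_i)`, so `y_reported <= y_true` always.
#'
#' In addition to the drawn covariates the table carries the derived column
#' `age_survey` (`25_34` vs `35_49`, from the simulated interview age) and
#' the simulation truth columns `y_true`, `lambda_true`, `phi_true`,
#' `pi_true`, which real data would not have.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `woman_id`, `y_reported`, `y_true`,
#'   `t_exposure`, `weight`, the covariates, and the truth columns.
#' @examples
#' resp <- simulate_respondents(fecond_like_preset(n_women = 200, seed = 3))
#' all(resp$y_reported <= resp$y_true)
#' @export
simulate_respondents <- function(config) {
  validate_sim_config(config)
  n <- config$n_women
  with_sim_seed(config$seed, {
    woman_covs <- setdiff(names(config$covariate_marginals), config$pregnancy_level)
    dat <- data.frame(woman_id = seq_len(n))
    for (nm in woman_covs)
      dat[[nm]] <- draw_categories(config$covariate_marginals[[nm]], n)

    menarche <- as.integer(draw_categories(config$ages$menarche, n))
    first_sex <- as.integer(draw_categories(config$ages$first_sex, n))
    interview <- as.integer(draw_categories(config$ages$interview, n))
    t_exp <- pmax(interview - pmin(menarche, first_sex), 0.5)
    dat$age_survey <- ifelse(interview <= 34, "25_34", "35_49")

    lambda <- exp(linear_predictor(config$beta_count, dat))
    phi <- plogis(linear_predictor(config$delta_zero, dat))
    pi <- plogis(linear_predictor(config$gamma_report, dat))

    y_true <- ifelse(runif(n) < phi, 0L, rpois(n, lambda * t_exp))
    y_rep <- rbinom(n, y_true, pi)

    dat$y_reported <- y_rep
    dat$y_true <- y_true
    dat$t_exposure <- t_exp
    dat$weight <- rlnorm(n, 0, 0.25)
    dat$lambda_true <- lambda
    dat$phi_true <- phi
    dat$pi_true <- pi
    front <- c("woman_id", "y_reported", "y_true", "t_exposure", "weight")
    dat[, c(front, setdiff(names(dat), front))]
  })
}

age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 19, 24, 29, 34, 39, Inf),
      labels = c("below_20", "20_24", "25_29", "30_34", "35_39", "40+"))
}

cap_2plus <- function(k) ifelse(k >= 2, "2+", as.character(k))

#' Simulate per-woman pregnancy sequences
#'
#' For each woman a random intercept `u_k ~ N(0, re_sd[k]^2)` is drawn once
#' per non-reference outcome, plus an optional shared frailty
#' `v ~ N(0, frailty_sd^2)`. The number of pregnancies follows a zero-inflated
#' Poisson whose mean is multiplied by `exp(v)`, so a positive `frailty_sd`
#' couples history length to outcome risk. Each pregnancy's outcome is drawn
#' from the multinomial logit with live birth as reference:
#' `eta_k = outcome_coefs[k]'x + u_k` (plus `v` for miscarriage). The running
#' covariates `prior_miscarriages` and `parity_at_start` are updated between
#' pregnancies from the simulated sequence itself.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per pregnancy: `woman_id`,
#'   `pregnancy_index`, `outcome` (`live_birth` / `miscarriage` /
#'   `abortion`), `age_group_at_start`, `prior_miscarriages`,
#'   `parity_at_start`, and the configured woman- and pregnancy-level
#'   covariates.
#' @examples
#' preg <- simulate_pregnancies(fecond_like_preset(n_women = 300, seed = 5))
#' table(preg$outcome)
#' @export
simulate_pregnancies <- function(config) {
  validate_sim_config(config)
  n <- config$n_women
  outs <- names(config$outcome_coefs)
  if (!all(c("miscarriage", "abortion") %in% outs))
    stop("`outcome_coefs` must contain `miscarriage` and `abortion`", call. = FALSE)
  with_sim_seed(config$seed + 1L, {
    woman_covs <- setdiff(names(config$covariate_marginals), config$pregnancy_level)
    women <- data.frame(woman_id = seq_len(n))
    for (nm in woman_covs)
      women[[nm]] <- draw_categories(config$covariate_marginals[[nm]], n)

    v <- if (config$frailty_sd > 0) rnorm(n, 0, config$frailty_sd) else numeric(n)
    u <- matrix(0, n, length(outs), dimnames = list(NULL, outs))
    for (k in outs) {
      sdk <- config$re_sd[[k]]
      if (!is.null(sdk) && sdk > 0) u[, k] <- rnorm(n, 0, sdk)
    }
    h <- config$history
    n_preg <- ifelse(runif(n) < h$zero_prob, 0L,
                     rpois(n, h$mean_pregnancies * exp(v)))
    n_preg <- pmin(n_preg, h$max_pregnancies)

    first_age <- pmin(pmax(round(rnorm(n, h$first_age_mean, h$first_age_sd)), 15), 42)
    prior_mis <- integer(n)
    parity <- integer(n)
    cur_age <- first_age

    rows <- vector("list", max(n_preg, 0))
    jmax <- if (length(n_preg)) max(n_preg) else 0L
    for (j in seq_len(jmax)) {
      act <- which(n_preg >= j)
      if (!length(act)) break
      dat <- women[act, , drop = FALSE]
      for (nm in config$pregnancy_level)
        dat[[nm]] <- draw_categories(config$covariate_marginals[[nm]], length(act))
      dat$age_group_at_start <- as.character(age_group_of(cur_age[act]))
      dat$prior_miscarriages <- cap_2plus(prior_mis[act])
      dat$parity_at_start <- cap_2plus(parity[act])

      eta <- matrix(0, length(act), length(outs),
                    dimnames = list(NULL, outs))
      for (k in outs) {
        e <- linear_predictor(config$outcome_coefs[[k]], dat) + u[act, k]
        if (k == "miscarriage") e <- e + v[act]
        eta[, k] <- e
      }
      # live birth is the reference: eta = 0
      em <- cbind(live_birth = 0, eta)
      p <- exp(em - apply(em, 1, max))
      p <- p / rowSums(p)
      # categorical draw via cumulative probabilities
      r <- runif(length(act))
      cum <- t(apply(p, 1, cumsum))
      idx <- rowSums(r > cum) + 1L
      idx[idx > ncol(p)] <- ncol(p)
      outcome <- colnames(em)[idx]

      dat$pregnancy_index <- j
      dat$outcome <- outcome
      rows[[j]] <- dat

      cur_age[act] <- cur_age[act] + 1L + rpois(length(act), max(h$spacing_mean - 1, 0))
      prior_mis[act] <- prior_mis[act] + (outcome == "miscarriage")
      parity[act] <- parity[act] + (outcome == "live_birth")
    }
    out <- do.call(rbind, rows[lengths(rows) > 0])
    if (is.null(out)) {
      out <- data.frame(woman_id = integer(), pregnancy_index = integer(),
                        outcome = character())
    }
    out <- out[order(out$woman_id, out$pregnancy_index), , drop = FALSE]
    rownames(out) <- NULL
    front <- c("woman_id", "pregnancy_index", "outcome", "age_group_at_start",
               "prior_miscarriages", "parity_at_start")
    out[, c(intersect(front, names(out)), setdiff(names(out), front))]
  })
}
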