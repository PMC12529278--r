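#' Specify the multilevel multinomial outcome model
#'
#' Three-category multinomial logistic regression of pregnancy outcome with
#' live birth (or another declared label) as the reference, optional
#' woman-level random intercepts `u_ik ~ N(0, sigma_k^2)` with a separate SD
#' per non-reference outcome, and Bayesian estimation by adaptive
#' Metropolis-within-Gibbs. Priors are weakly informative: Normal(0, 5^2) on
#' fixed effects and half-Student-t(3, scale 2.5) on the random-intercept
#' SDs.
#'
#' @param covariates Character vector of (categorical) covariate names.
#' @param outcomes Non-reference outcome labels, in order (linear predictors
#'   `eta_1`, `eta_2`).
#' @param reference Reference outcome label.
#' @param include_random_effects Logical; `FALSE` fits the pooled model with
#'   `u = 0` and additionally stores a maximum-a-posteriori estimate.
#' @param chains Number of Markov chains (at least 2).
#' @param iter Total iterations per chain (including warmup).
#' @param warmup Warmup (adaptation) iterations; adaptation is frozen
#'   afterwards. Default: half of `iter`.
#' @param seed Integer seed; identical spec and data give identical draws.
#' @param prior List: `beta_sd`, `sigma_df`, `sigma_scale`.
#' @return An object of class `mnl_spec`.
#' @export
mnl_spec <- function(covariates,
                     outcomes = c("miscarriage", "abortion"),
                     reference = "live_birth",
                     include_random_effects = TRUE,
                     chains = 4, iter = 6000, warmup = floor(iter / 2),
                     seed = 1L,
                     prior = list(beta_sd = 5, sigma_df = 3, sigma_scale = 2.5)) {
  if (length(outcomes) != 2)
    stop("exactly two non-reference outcomes are supported", call. = FALSE)
  if (reference %in% outcomes)
    stop("the reference label must not appear in `outcomes`", call. = FALSE)
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (iter <= warmup) stop("`iter` must exceed `warmup`", call. = FALSE)
  prior <- modifyList(list(beta_sd = 5, sigma_df = 3, sigma_scale = 2.5), prior)
  structure(list(covariates = as.character(covariates), outcomes = outcomes,
                 reference = reference,
                 include_random_effects = include_random_effects,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 prior = prior),
            class = "mnl_spec")
}

log_half_t <- function(sigma, df, scale) {
  log(2) + stats::dt(sigma / scale, df, log = TRUE) - log(scale)
}

# One chain of the adaptive Metropolis-within-Gibbs sampler. Fixed-effect
# blocks use a multivariate random walk whose covariance is re-estimated from
# the warmup history; woman-level intercepts are updated jointly with
# per-woman accept/reject; SDs move on the log scale. All adaptation stops at
# the end of warmup.
run_mnl_chain <- function(X, ychosen, wid, n_w, spec, chain_seed, init_beta) {
  set.seed(chain_seed)
  n <- nrow(X)
  p <- ncol(X)
  re <- spec$include_random_effects
  pr <- spec$prior
  iter <- spec$iter; warmup <- spec$warmup
  kept <- iter - warmup

  B <- init_beta + matrix(rnorm(2 * p, 0, 0.1), p, 2)
  U <- matrix(0, n_w, 2)
  ls <- c(0, 0)                       # log sigma_u
  eta <- X %*% B
  if (re) eta <- eta + U[wid, ]

  loglik_from <- function(eta) {
    denom <- log_denom(eta[, 1], eta[, 2])
    ec <- numeric(n)
    for (j in 1:2) ec[ychosen == j] <- eta[ychosen == j, j]
    sum(ec) - sum(denom)
  }
  lp_rows <- function(eta) {
    denom <- log_denom(eta[, 1], eta[, 2])
    ec <- numeric(n)
    for (j in 1:2) ec[ychosen == j] <- eta[ychosen == j, j]
    ec - denom
  }
  cur_ll <- loglik_from(eta)

  # adaptation state: per-block scalar scales (Robbins-Monro toward target
  # acceptance) and a proposal covariance for the fixed-effect blocks
  # re-estimated from the warmup history
  lsc <- rep(log(0.1), 2)             # beta block scales
  Lk <- list(diag(p), diag(p))
  lsu <- c(log(0.5), log(0.5))        # u scales
  lss <- c(log(0.3), log(0.3))        # log-sigma scales (centered step)
  lsn <- c(log(0.2), log(0.2))        # log-sigma scales (non-centered step)
  acc <- list(beta = c(0, 0), u = c(0, 0), s = c(0, 0), n = c(0, 0))
  batch <- 25
  hist_beta <- list(matrix(NA_real_, warmup, p), matrix(NA_real_, warmup, p))

  draws_beta <- array(NA_real_, c(kept, p, 2))
  draws_sigma <- matrix(NA_real_, kept, 2)
  draws_lp <- numeric(kept)

  for (it in seq_len(iter)) {
    for (k in 1:2) {
      prop <- B[, k] + exp(lsc[k]) * drop(Lk[[k]] %*% rnorm(p))
      eta_prop <- eta
      eta_prop[, k] <- eta[, k] + drop(X %*% (prop - B[, k]))
      ll_prop <- loglik_from(eta_prop)
      dprior <- sum(stats::dnorm(prop, 0, pr$beta_sd, log = TRUE)) -
        sum(stats::dnorm(B[, k], 0, pr$beta_sd, log = TRUE))
      if (log(runif(1)) < ll_prop - cur_ll + dprior) {
        B[, k] <- prop; eta <- eta_prop; cur_ll <- ll_prop
        acc$beta[k] <- acc$beta[k] + 1
      }
      if (it <= warmup) hist_beta[[k]][it, ] <- B[, k]
    }

    if (re) {
      lp_cur <- lp_rows(eta)
      for (k in 1:2) {
        sig <- exp(ls[k])
        u_prop <- U[, k] + exp(lsu[k]) * rnorm(n_w)
        eta_prop <- eta
        eta_prop[, k] <- eta[, k] + (u_prop - U[, k])[wid]
        lp_prop <- lp_rows(eta_prop)
        dll_w <- rowsum(lp_prop - lp_cur, wid, reorder = TRUE)
        dpr_w <- stats::dnorm(u_prop, 0, sig, log = TRUE) -
          stats::dnorm(U[, k], 0, sig, log = TRUE)
        acc_w <- log(runif(n_w)) < drop(dll_w) + dpr_w
        if (any(acc_w)) {
          U[acc_w, k] <- u_prop[acc_w]
          sel <- acc_w[wid]
          eta[sel, k] <- eta_prop[sel, k]
          lp_cur[sel] <- lp_prop[sel]
        }
        acc$u[k] <- acc$u[k] + mean(acc_w)

        # centered step: log-sigma random walk given current u
        ls_prop <- ls[k] + exp(lss[k]) * rnorm(1)
        tgt <- function(l) sum(stats::dnorm(U[, k], 0, exp(l), log = TRUE)) +
          log_half_t(exp(l), pr$sigma_df, pr$sigma_scale) + l
        if (log(runif(1)) < tgt(ls_prop) - tgt(ls[k])) {
          ls[k] <- ls_prop
          acc$s[k] <- acc$s[k] + 1
        }

        # non-centered (interweaving) step: hold z = u / sigma fixed and
        # move sigma, rescaling u; breaks the u-sigma funnel when the
        # intercepts are weakly informed per woman
        ls_prop <- ls[k] + exp(lsn[k]) * rnorm(1)
        scale_f <- exp(ls_prop - ls[k])
        u_prop <- U[, k] * scale_f
        eta_prop <- eta
        eta_prop[, k] <- eta[, k] + (u_prop - U[, k])[wid]
        ll_prop <- loglik_from(eta_prop)
        cur_ll <- loglik_from(eta)
        dtgt <- ll_prop - cur_ll +
          log_half_t(exp(ls_prop), pr$sigma_df, pr$sigma_scale) -
          log_half_t(exp(ls[k]), pr$sigma_df, pr$sigma_scale) +
          ls_prop - ls[k]
        if (log(runif(1)) < dtgt) {
          ls[k] <- ls_prop
          U[, k] <- u_prop
          eta <- eta_prop
          acc$n[k] <- acc$n[k] + 1
        }
      }
      cur_ll <- loglik_from(eta)
    }

    if (it <= warmup && it %% batch == 0) {
      d <- min(0.3, 5 / sqrt(it))
      for (k in 1:2) {
        lsc[k] <- lsc[k] + d * sign(acc$beta[k] / batch - 0.234)
        lsu[k] <- lsu[k] + d * sign(acc$u[k] / batch - 0.44)
        lss[k] <- lss[k] + d * sign(acc$s[k] / batch - 0.44)
        lsn[k] <- lsn[k] + d * sign(acc$n[k] / batch - 0.44)
      }
      acc <- list(beta = c(0, 0), u = c(0, 0), s = c(0, 0), n = c(0, 0))
      if (it >= 200 && it %% 200 == 0) {
        for (k in 1:2) {
          cv <- stats::cov(hist_beta[[k]][max(1, it - 399):it, , drop = FALSE])
          ch <- tryCatch(chol(cv + diag(1e-8, p)), error = function(e) NULL)
          if (!is.null(ch)) {
            Lk[[k]] <- t(ch)
            lsc[k] <- log(2.38 / sqrt(p))  # restart at the Gaussian-optimal scale
          }
        }
      }
    }

    if (it > warmup) {
      j <- it - warmup
      draws_beta[j, , ] <- B
      draws_sigma[j, ] <- exp(ls)
      lpost <- cur_ll +
        sum(stats::dnorm(B, 0, pr$beta_sd, log = TRUE))
      if (re) lpost <- lpost +
          sum(stats::dnorm(U, 0, rep(exp(ls), each = n_w), log = TRUE)) +
          sum(log_half_t(exp(ls), pr$sigma_df, pr$sigma_scale))
      draws_lp[j] <- lpost
    }
  }
  list(beta = draws_beta, sigma = draws_sigma, lp = draws_lp)
}

split_rhat <- function(m) {
  # m: iterations x chains; split each chain in half
  n <- floor(nrow(m) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(m[seq_len(n), , drop = FALSE],
                  m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, var)
  W <- mean(s2)
  Bv <- n * var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

ess_basic <- function(m) {
  n <- nrow(m); C <- ncol(m)
  lag_max <- min(200, n - 2)
  rho <- rowMeans(sapply(seq_len(C), function(c) {
    a <- stats::acf(m[, c], lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
    as.numeric(a)
  }))
  # Geyer-style truncation at the first negative paired sum
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  n * C / (1 + 2 * s)
}

#' Fit the multilevel multinomial outcome model by MCMC
#'
#' Samples the joint posterior of the fixed effects, the woman-level random
#' intercepts and their SDs with the package's adaptive
#' Metropolis-within-Gibbs sampler (see [mnl_spec()] for priors and
#' defaults). With `include_random_effects = FALSE` the random intercepts are
#' fixed at zero and a maximum-a-posteriori estimate (direct optimisation of
#' the log posterior) is additionally stored in `$map`.
#'
#' Convergence diagnostics (split-Rhat and effective sample size) are
#' computed for every reported parameter; if any Rhat exceeds 1.05 or any ESS
#' falls below 100 the fit is returned with `diag_ok = FALSE` and a prominent
#' warning, never silently.
#'
#' @param pregnancies Pregnancy data frame (one row per pregnancy, columns
#'   `woman_id`, `outcome` and the covariates).
#' @param spec An [mnl_spec()].
#' @return An object of class `mnl_fit`: `summary` (mean, SD, quantiles,
#'   Rhat, ESS per parameter), `beta_draws` (per outcome: total draws x
#'   coefficients), `sigma_draws`, `lp_draws`, `chain_id`, `map` (no-RE
#'   only), `levels`, `spec`, `data`, `diag_ok`.
#' @examples
#' \donttest{
#' cfg <- fecond_like_preset(n_women = 300, seed = 4)
#' preg <- simulate_pregnancies(cfg)
#' sp <- mnl_spec("age_group_at_start", chains = 2, iter = 600, seed = 2)
#' fit <- fit_risk_model(preg, sp)
#' head(fit$summary)
#' }
#' @export
fit_risk_model <- function(pregnancies, spec) {
  stopifnot(inherits(spec, "mnl_spec"))
  need <- c("woman_id", "outcome", spec$covariates)
  miss <- setdiff(need, names(pregnancies))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(pregnancies[, need, drop = FALSE])
  if (any(!keep))
    message(sprintf("dropped %d of %d pregnancies with missing values",
                    sum(!keep), length(keep)))
  dat <- pregnancies[keep, , drop = FALSE]
  out <- as.character(dat$outcome)
  present <- unique(out)
  labels <- c(spec$outcomes, spec$reference)
  bad <- setdiff(present, labels)
  if (length(bad))
    stop("outcome labels not declared in the spec: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(present) < 2)
    stop(sprintf("degenerate outcome data: only `%s` observed", present[1]),
         call. = FALSE)

  levels <- covariate_levels(dat, spec$covariates)
  X <- build_design(dat, spec$covariates, levels)
  p <- ncol(X)
  ychosen <- match(out, spec$outcomes, nomatch = 0L)  # 0 = reference
  ids <- sort(unique(as.character(dat$woman_id)), method = "radix")
  wid <- match(as.character(dat$woman_id), ids)
  n_w <- length(ids)

  # MAP of the no-random-effect posterior, also used to initialise chains
  negpost <- function(theta) {
    Bm <- matrix(theta, p, 2)
    eta <- X %*% Bm
    denom <- log_denom(eta[, 1], eta[, 2])
    ec <- numeric(nrow(X))
    for (j in 1:2) ec[ychosen == j] <- eta[ychosen == j, j]
    -(sum(ec) - sum(denom) +
        sum(stats::dnorm(theta, 0, spec$prior$beta_sd, log = TRUE)))
  }
  opt <- optim(numeric(2 * p), negpost, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-10))
  map_mat <- matrix(opt$par, p, 2,
                    dimnames = list(colnames(X), spec$outcomes))

  chain_seeds <- spec$seed + 7919L * seq_len(spec$chains)
  chains <- lapply(chain_seeds, function(cs)
    run_mnl_chain(X, ychosen, wid, n_w, spec, cs, map_mat))

  kept <- spec$iter - spec$warmup
  par_names <- c(
    unlist(lapply(spec$outcomes, function(k) paste(k, colnames(X), sep = "."))),
    if (spec$include_random_effects) paste0("sigma_u.", spec$outcomes)
  )
  # iterations x chains matrix per parameter
  mat_of <- function(f) sapply(chains, f)
  param_mats <- list()
  for (k in 1:2) for (j in seq_len(p))
    param_mats[[paste(spec$outcomes[k], colnames(X)[j], sep = ".")]] <-
      mat_of(function(ch) ch$beta[, j, k])
  if (spec$include_random_effects)
    for (k in 1:2)
      param_mats[[paste0("sigma_u.", spec$outcomes[k])]] <-
        mat_of(function(ch) ch$sigma[, k])

  summ <- do.call(rbind, lapply(par_names, function(nm) {
    m <- param_mats[[nm]]
    v <- as.numeric(m)
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               q2.5 = quantile(v, 0.025, names = FALSE),
               q97.5 = quantile(v, 0.975, names = FALSE),
               rhat = split_rhat(m), ess = ess_basic(m),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  diag_ok <- all(summ$rhat < 1.05, na.rm = TRUE) && all(summ$ess >= 100)
  if (!diag_ok)
    warning(paste("MCMC diagnostics flag possible non-convergence",
                  "(some split-Rhat > 1.05 or ESS < 100); inspect $summary"),
            call. = FALSE)

  beta_draws <- lapply(seq_len(2), function(k) {
    d <- do.call(rbind, lapply(chains, function(ch) ch$beta[, , k]))
    colnames(d) <- colnames(X)
    d
  })
  names(beta_draws) <- spec$outcomes
  sigma_draws <- do.call(rbind, lapply(chains, function(ch) ch$sigma))
  colnames(sigma_draws) <- spec$outcomes
  if (!spec$include_random_effects) sigma_draws[] <- 0

  structure(list(
    summary = summ,
    beta_draws = beta_draws,
    sigma_draws = sigma_draws,
    lp_draws = unlist(lapply(chains, function(ch) ch$lp)),
    chain_id = rep(seq_len(spec$chains), each = kept),
    map = if (!spec$include_random_effects) map_mat else NULL,
    levels = levels, spec = spec, data = dat, diag_ok = diag_ok
  ), class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat(sprintf("Multinomial outcome model (%s random intercepts), %d chains x %d iterations\n",
              if (x$spec$include_random_effects) "with" else "without",
              x$spec$chains, x$spec$iter))
  cat(sprintf("  %d pregnancies, %d women, diagnostics %s\n",
              nrow(x$data), length(unique(x$data$woman_id)),
              if (x$diag_ok) "clean" else "FLAGGED"))
  print(cbind(x$summary[, "parameter", drop = FALSE],
              round(x$summary[, -1], 3)), row.names = FALSE)
  invisible(x)
}

#' Marginally standardised predicted outcome probabilities
#'
#' For each requested level of a focal covariate, predicts the probability of
#' each outcome by marginal standardisation: for every (thinned) posterior
#' draw, the focal covariate is set to that level in all observed pregnancy
#' rows, outcome probabilities are averaged over the rows and - when the
#' model has random intercepts - over fresh Monte Carlo draws of
#' `u_k ~ N(0, sigma_k)` using that posterior draw's SDs. The 95% credible
#' interval is the 2.5/97.5 percentile of the draw-level averages.
#'
#' @param fit An [fit_risk_model()] result.
#' @param profile_var Name of the focal covariate.
#' @param levels Levels to predict at (default: all levels seen at fit time;
#'   an unseen level is an error).
#' @param n_u Monte Carlo draws of the random intercept per posterior draw
#'   (default 200; ignored without random effects).
#' @param max_draws Posterior draws used (evenly thinned; default 300).
#' @param seed Seed for the random-intercept draws.
#' @return Data frame with columns `profile`, `outcome`, `mean`, `lower`,
#'   `upper` (probabilities).
#' @export
predict_probabilities <- function(fit, profile_var, levels = NULL,
                                  n_u = 200, max_draws = 300, seed = 1L) {
  stopifnot(inherits(fit, "mnl_fit"))
  if (!profile_var %in% fit$spec$covariates)
    stop(sprintf("`%s` is not a covariate of the fitted model", profile_var),
         call. = FALSE)
  known <- fit$levels[[profile_var]]
  if (is.null(levels)) levels <- known
  unseen <- setdiff(levels, known)
  if (length(unseen))
    stop(sprintf("unseen category `%s` for covariate `%s`",
                 unseen[1], profile_var), call. = FALSE)
  re <- fit$spec$include_random_effects
  n_draws_total <- nrow(fit$beta_draws[[1]])
  take <- unique(round(seq(1, n_draws_total, length.out = min(max_draws, n_draws_total))))
  outs <- c(fit$spec$outcomes, fit$spec$reference)

  res <- list()
  with_sim_seed(seed, {
    for (lv in levels) {
      dat <- fit$data
      dat[[profile_var]] <- lv
      X <- build_design(dat, fit$spec$covariates, fit$levels)
      pmat <- matrix(NA_real_, length(take), 3)
      for (d in seq_along(take)) {
        i <- take[d]
        eta1 <- drop(X %*% fit$beta_draws[[1]][i, ])
        eta2 <- drop(X %*% fit$beta_draws[[2]][i, ])
        if (re && any(fit$sigma_draws[i, ] > 0)) {
          u1 <- rnorm(n_u, 0, fit$sigma_draws[i, 1])
          u2 <- rnorm(n_u, 0, fit$sigma_draws[i, 2])
          e1 <- outer(eta1, u1, "+")
          e2 <- outer(eta2, u2, "+")
          m <- pmax(e1, e2, 0)
          x1 <- exp(e1 - m); x2 <- exp(e2 - m); x3 <- exp(-m)
          s <- x1 + x2 + x3
          pmat[d, ] <- c(mean(x1 / s), mean(x2 / s), mean(x3 / s))
        } else {
          pr <- outcome_probs(eta1, eta2)
          pmat[d, ] <- colMeans(pr)
        }
      }
      for (j in 1:3) {
        res[[length(res) + 1]] <- data.frame(
          profile = lv, outcome = outs[j],
          mean = mean(pmat[, j]),
          lower = quantile(pmat[, j], 0.025, names = FALSE),
          upper = quantile(pmat[, j], 0.975, names = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
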