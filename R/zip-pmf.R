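#' Zero-inflated Poisson log probability mass
#'
#' Log probability of observing count `y` under a zero-inflated Poisson with
#' Poisson mean `lambda_t` (the rate already multiplied by exposure time) and
#' structural-zero probability `phi`:
#' \deqn{P(Y = 0) = \phi + (1-\phi) e^{-\lambda t}}
#' \deqn{P(Y = y \mid y > 0) = (1-\phi)\frac{(\lambda t)^y e^{-\lambda t}}{y!}}
#'
#' All arguments are recycled to a common length. `-Inf` is a valid return
#' (e.g. `phi = 1` with `y > 0`).
#'
#' @param y Nonnegative integer count(s).
#' @param lambda_t Positive Poisson mean(s), rate times exposure.
#' @param phi Zero-inflation probability in `[0, 1]`.
#' @return Log probabilities, same length as the recycled inputs.
#' @seealso [observed_logpmf()] for the binomially thinned version.
#' @examples
#' zip_logpmf(0, 1, 0.3)  # log(0.3 + 0.7 * exp(-1))
#' zip_logpmf(1, 1, 0)    # plain Poisson: -1
#' @export
zip_logpmf <- function(y, lambda_t, phi) {
  n <- max(length(y), length(lambda_t), length(phi))
  y <- rep_len(y, n)
  lambda_t <- rep_len(lambda_t, n)
  phi <- rep_len(phi, n)
  if (any(y < 0) || any(y != floor(y)))
    stop("`y` must contain nonnegative integers", call. = FALSE)
  if (any(lambda_t <= 0))
    stop("`lambda_t` must be strictly positive", call. = FALSE)
  if (any(phi < 0 | phi > 1))
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  out <- numeric(n)
  zero <- y == 0
  # P(0) = phi + (1 - phi) exp(-lt), computed in log space to keep accuracy
  # when both terms are tiny
  if (any(zero)) {
    lp_pois0 <- -lambda_t[zero]
    p0 <- phi[zero]
    out[zero] <- ifelse(
      p0 == 0, lp_pois0,
      ifelse(p0 == 1, 0, log(p0 + (1 - p0) * exp(lp_pois0)))
    )
  }
  if (any(!zero)) {
    p1 <- phi[!zero]
    out[!zero] <- ifelse(
      p1 == 1, -Inf,
      log1p(-p1) + dpois(y[!zero], lambda_t[!zero], log = TRUE)
    )
  }
  out
}

#' Log probability mass of the reported (thinned) count
#'
#' Each of the `Y*` true events, drawn from a zero-inflated Poisson with mean
#' `lambda_t` and inflation `phi`, is independently reported with probability
#' `pi`; the reported count is `Y ~ Binomial(Y*, pi)`. Marginally the thinned
#' count is again zero-inflated Poisson with Poisson mean `pi * lambda_t` and
#' the same `phi`, which is the closed form evaluated here.
#'
#' @inheritParams zip_logpmf
#' @param pi Reporting probability in `[0, 1]`. `pi = 0` puts all mass at
#'   zero.
#' @return Log probabilities.
#' @examples
#' observed_logpmf(0, 1, 0.3, 0.5)  # log(0.3 + 0.7 * exp(-0.5))
#' @export
observed_logpmf <- function(y, lambda_t, phi, pi) {
  n <- max(length(y), length(lambda_t), length(phi), length(pi))
  y <- rep_len(y, n)
  lambda_t <- rep_len(lambda_t, n)
  phi <- rep_len(phi, n)
  pi <- rep_len(pi, n)
  if (any(pi < 0 | pi > 1))
    stop("`pi` must lie in [0, 1]", call. = FALSE)
  if (any(lambda_t <= 0))
    stop("`lambda_t` must be strictly positive", call. = FALSE)
  out <- numeric(n)
  degenerate <- pi == 0  # nothing is ever reported
  if (any(degenerate)) {
    if (any(y < 0 | y != floor(y)))
      stop("`y` must contain nonnegative integers", call. = FALSE)
    out[degenerate] <- ifelse(y[degenerate] == 0, 0, -Inf)
  }
  if (any(!degenerate)) {
    out[!degenerate] <- zip_logpmf(
      y[!degenerate], pi[!degenerate] * lambda_t[!degenerate], phi[!degenerate]
    )
  }
  out
}
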