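#' Multinomial outcome probabilities from two linear predictors
#'
#' Probabilities of the three pregnancy outcomes given the linear predictors
#' of the two non-reference outcomes (the reference has linear predictor 0):
#' \deqn{P(Y = k) = \frac{e^{\eta_k}}{1 + e^{\eta_1} + e^{\eta_2}}}
#' computed with overflow-safe normalisation, so extreme inputs (|eta| of
#' several hundred) return valid probabilities summing to one.
#'
#' @param eta_1,eta_2 Finite linear predictors (vectorised).
#' @return For scalar input, a numeric vector `(p1, p2, p_ref)`; for vector
#'   input, a matrix with those three columns.
#' @examples
#' outcome_probs(log(2), 0)  # (0.5, 0.25, 0.25)
#' @export
outcome_probs <- function(eta_1, eta_2) {
  if (any(!is.finite(eta_1)) || any(!is.finite(eta_2)))
    stop("linear predictors must be finite", call. = FALSE)
  n <- max(length(eta_1), length(eta_2))
  em <- cbind(rep_len(eta_1, n), rep_len(eta_2, n), 0)
  m <- pmax(em[, 1], em[, 2], 0)
  ex <- exp(em - m)
  p <- ex / rowSums(ex)
  colnames(p) <- NULL
  if (length(eta_1) == 1 && length(eta_2) == 1) drop(p) else p
}

# log denominator log(1 + e^eta1 + e^eta2), stable
log_denom <- function(eta1, eta2) {
  m <- pmax(eta1, eta2, 0)
  m + log(exp(-m) + exp(eta1 - m) + exp(eta2 - m))
}

#' Conditional log-likelihood of a multinomial outcome model
#'
#' Sum over pregnancies of the log probability of the realised outcome under
#' the multinomial logit `eta_k = coef_k' x + u[woman, k]` with the reference
#' outcome's predictor fixed at zero.
#'
#' @param pregnancies Data frame with `outcome`, `woman_id` and the
#'   covariates referenced by the coefficients.
#' @param params Named list of coefficient vectors, one per non-reference
#'   outcome (names `"(Intercept)"` / `"covariate:level"` as in
#'   [sim_config()]).
#' @param u Matrix of woman-level effects: one row per woman (rownames =
#'   woman ids), one column per non-reference outcome. Every pregnancy's
#'   woman must have a row.
#' @param reference Label of the reference outcome (default `"live_birth"`).
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(pregnancies, params, u = NULL,
                               reference = "live_birth") {
  ks <- names(params)
  if (is.null(ks) || length(ks) != 2)
    stop("`params` must name exactly two non-reference outcomes", call. = FALSE)
  n <- nrow(pregnancies)
  if (is.null(u)) {
    ids <- unique(pregnancies$woman_id)
    u <- matrix(0, length(ids), 2, dimnames = list(ids, ks))
  }
  idx <- match(as.character(pregnancies$woman_id), rownames(u))
  if (anyNA(idx))
    stop("some pregnancies have no woman-level effect entry: woman_id ",
         paste(head(unique(pregnancies$woman_id[is.na(idx)]), 3), collapse = ", "),
         call. = FALSE)
  eta <- matrix(0, n, 2, dimnames = list(NULL, ks))
  for (k in ks)
    eta[, k] <- linear_predictor(params[[k]], pregnancies) + u[idx, k]
  denom <- log_denom(eta[, 1], eta[, 2])
  out <- as.character(pregnancies$outcome)
  bad <- setdiff(unique(out), c(ks, reference))
  if (length(bad))
    stop("unknown outcome labels: ", paste(bad, collapse = ", "), call. = FALSE)
  eta_chosen <- numeric(n)
  for (j in 1:2) eta_chosen[out == ks[j]] <- eta[out == ks[j], j]
  sum(eta_chosen - denom)
}
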