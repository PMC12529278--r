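#' Candidate set of BT-ZIP specifications
#'
#' @param ... Named [btzip_spec()] objects (or a single named list). Names
#'   are the candidate labels and must be unique.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && !inherits(specs[[1]], "btzip_spec"))
    specs <- specs[[1]]
  if (is.null(names(specs)) || any(names(specs) == "") ||
      anyDuplicated(names(specs)))
    stop("candidates must have unique names", call. = FALSE)
  for (nm in names(specs)) {
    if (!inherits(specs[[nm]], "btzip_spec"))
      stop(sprintf("candidate `%s` is not a btzip_spec", nm), call. = FALSE)
    specs[[nm]]$label <- nm
  }
  structure(specs, class = "candidate_set")
}

#' Fit every candidate specification on a shared complete-case sample
#'
#' The analysis rows are fixed once, as the complete cases over the union of
#' all candidates' covariates, so AIC/BIC are computed on identical
#' observations and are comparable across candidates. A candidate that
#' references absent columns is marked invalid and the others proceed; a
#' candidate that fails to converge is recorded as such, never raised.
#'
#' @param data Respondent data frame.
#' @param candidates A [candidate_set()].
#' @param control Optimizer control passed to [btzip_fit()].
#' @return Named list of `btzip_fit` objects (or `NULL` for invalid
#'   candidates), with attribute `n_obs` (shared sample size).
#' @export
fit_candidates <- function(data, candidates, control = list()) {
  stopifnot(inherits(candidates, "candidate_set"))
  all_covs <- unique(unlist(lapply(candidates, function(s)
    c(s$count_covariates, s$zero_covariates, s$report_covariates))))
  usable <- intersect(all_covs, names(data))
  shared <- btzip_prepare(data, usable, quiet = TRUE)
  fits <- lapply(candidates, function(spec) {
    covs <- unique(c(spec$count_covariates, spec$zero_covariates,
                     spec$report_covariates))
    if (length(setdiff(covs, names(shared)))) return(NULL)
    degenerate <- vapply(covs, function(cv)
      length(unique(as.character(shared[[cv]]))) < 2, logical(1))
    fit <- tryCatch(
      suppressWarnings(btzip_fit(shared, spec, control)),
      error = function(e) NULL)
    if (!is.null(fit) && any(degenerate)) fit$converged <- FALSE
    fit
  })
  attr(fits, "n_obs") <- nrow(shared)
  fits
}

#' Robustness table of average reporting rates across specifications
#'
#' One row per converged candidate: its average reporting rate on the shared
#' sample, AIC, BIC, and flags for the AIC- and BIC-best candidates. Ranking
#' ties are broken lexicographically by label.
#'
#' @param fits Output of [fit_candidates()].
#' @param data Respondent data frame (the shared sample used for averaging).
#' @return Data frame with columns `label`, `avg_reporting_rate` (percent),
#'   `aic`, `bic`, `converged`, `best_aic`, `best_bic`, ordered by AIC.
#' @export
robustness_table <- function(fits, data) {
  rows <- list()
  for (lab in names(fits)) {
    fit <- fits[[lab]]
    if (is.null(fit)) next
    rate <- if (fit$converged)
      average_reporting_rate(fit, data)$rate[1] else NA_real_
    rows[[lab]] <- data.frame(label = lab, avg_reporting_rate = rate,
                              aic = fit$aic, bic = fit$bic,
                              converged = fit$converged,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no candidate could be fitted", call. = FALSE)
  out <- do.call(rbind, rows)
  conv <- out[out$converged, , drop = FALSE]
  if (!nrow(conv))
    stop("no candidate converged", call. = FALSE)
  pick <- function(crit) {
    o <- order(conv[[crit]], conv$label, method = "radix")
    conv$label[o[1]]
  }
  out$best_aic <- out$converged & out$label == pick("aic")
  out$best_bic <- out$converged & out$label == pick("bic")
  out <- out[order(out$aic, out$label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
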