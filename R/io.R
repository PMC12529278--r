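# Reading and writing the pipeline's tables. Readers are strict about the
# header, reject malformed rows with their line numbers, and count every
# exclusion so input rows always reconcile as used + excluded.

check_header <- function(found, required, what) {
  miss <- setdiff(required, found)
  if (length(miss))
    stop(sprintf("%s: wrong header; expected columns {%s}, found {%s}",
                 what, paste(required, collapse = ", "),
                 paste(found, collapse = ", ")), call. = FALSE)
}

#' Read and validate a respondent table
#'
#' Expects the CSV schema written by [write_respondents()]: `woman_id`,
#' `y_reported`, `t_exposure`, `weight` plus covariate columns (`y_true` and
#' the other simulation-truth columns are optional). Rows with a missing or
#' negative reported count, a non-integer count, or missing exposure are
#' rejected with their line numbers; the exclusion tally is attached as
#' attribute `exclusions` and logged.
#'
#' @param path CSV file path.
#' @return Validated data frame of respondents.
#' @export
read_respondents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(dat)) stop("empty respondent file: ", path, call. = FALSE)
  check_header(names(dat), c("woman_id", "y_reported", "t_exposure", "weight"),
               "respondent table")
  y <- suppressWarnings(as.numeric(dat$y_reported))
  t <- suppressWarnings(as.numeric(dat$t_exposure))
  bad <- is.na(y) | y < 0 | y != floor(y) | is.na(t)
  dat$y_reported <- y
  dat$t_exposure <- t
  if (any(bad))
    message(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(head(which(bad) + 1L, 10), collapse = ", ")))
  out <- dat[!bad, , drop = FALSE]
  attr(out, "exclusions") <- c(malformed = sum(bad))
  out
}

#' Read and validate a pregnancy table
#'
#' Expects the schema written by [write_pregnancies()]: `woman_id`,
#' `pregnancy_index`, `outcome` plus covariate columns. Rows with a missing
#' outcome or woman id are rejected with line numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame of pregnancies.
#' @export
read_pregnancies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(dat)) stop("empty pregnancy file: ", path, call. = FALSE)
  check_header(names(dat), c("woman_id", "pregnancy_index", "outcome"),
               "pregnancy table")
  bad <- is.na(dat$outcome) | dat$outcome == "" | is.na(dat$woman_id)
  if (any(bad))
    message(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(head(which(bad) + 1L, 10), collapse = ", ")))
  out <- dat[!bad, , drop = FALSE]
  attr(out, "exclusions") <- c(malformed = sum(bad))
  out
}

#' Write the pipeline's tables
#'
#' Plain CSV writers for the respondent and pregnancy tables (schema in
#' [simulate_respondents()] / [simulate_pregnancies()]) and a JSON writer for
#' a fitted BT-ZIP model (coefficients, covariance, log-likelihood, AIC/BIC,
#' convergence).
#'
#' @param data Data frame to write.
#' @param fit A [btzip_fit()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_respondents
#' @export
write_pregnancies <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_respondents
#' @export
write_btzip_fit <- function(fit, path) {
  stopifnot(inherits(fit, "btzip_fit"))
  x <- list(beta = as.list(fit$beta), delta = as.list(fit$delta),
            gamma = as.list(fit$gamma),
            vcov = fit$vcov, loglik = fit$loglik, aic = fit$aic,
            bic = fit$bic, n_obs = fit$n_obs, converged = fit$converged,
            n_starts_used = fit$n_starts_used)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
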