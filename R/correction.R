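#' Outcome distribution container
#'
#' Ordered outcome labels with their percentage shares (summing to 100 up to
#' one-decimal rounding of the inputs) and an optional pregnancy total.
#'
#' @param shares Named numeric vector of percentages.
#' @param total_pregnancies Optional integer count behind the shares.
#' @return An object of class `outcome_distribution`.
#' @export
outcome_distribution <- function(shares, total_pregnancies = NULL) {
  if (is.null(names(shares)) || any(names(shares) == ""))
    stop("`shares` must be fully named", call. = FALSE)
  if (any(shares < 0)) stop("shares must be nonnegative", call. = FALSE)
  if (abs(sum(shares) - 100) > 0.15)
    stop(sprintf("shares sum to %.3f, not 100 (tolerance 0.15 for rounded input)",
                 sum(shares)), call. = FALSE)
  structure(list(shares = shares,
                 total_pregnancies = total_pregnancies),
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat("Pregnancy outcome distribution (%)\n")
  print(round(x$shares, 1))
  if (!is.null(x$total_pregnancies))
    cat("total pregnancies:", x$total_pregnancies, "\n")
  invisible(x)
}

#' Correct an outcome distribution for underreporting
#'
#' Divides each reported share by its outcome-specific reporting rate and
#' renormalises so the corrected shares sum to 100:
#' \deqn{s_k^{corr} = \frac{s_k / r_k}{\sum_j s_j / r_j} \times 100}
#' Outcomes absent from `rates` are assumed correctly reported (rate 100%).
#' Full precision is kept internally; round only for display.
#'
#' @param reported An [outcome_distribution()] of reported shares.
#' @param rates Named numeric vector of reporting rates in percent, in
#'   (0, 100]; names must be a subset of the distribution's labels.
#' @return An [outcome_distribution()] of corrected shares.
#' @examples
#' rep <- outcome_distribution(c(miscarriage = 13.9, abortion = 10.3,
#'                               live_birth = 72.8, other = 3.0))
#' correct_distribution(rep, c(miscarriage = 92, abortion = 55))
#' @export
correct_distribution <- function(reported, rates) {
  stopifnot(inherits(reported, "outcome_distribution"))
  labels <- names(reported$shares)
  if (is.null(names(rates)) || any(names(rates) == ""))
    stop("`rates` must be named", call. = FALSE)
  unknown <- setdiff(names(rates), labels)
  if (length(unknown))
    stop("rates refer to unknown outcomes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full <- setNames(rep(100, length(labels)), labels)
  full[names(rates)] <- rates
  if (any(full <= 0) || any(full > 100))
    stop("reporting rates must lie in (0, 100]", call. = FALSE)
  adj <- reported$shares / (full / 100)
  corrected <- 100 * adj / sum(adj)
  outcome_distribution(corrected, reported$total_pregnancies)
}

#' Tabulate pregnancy outcomes as percentage shares
#'
#' Counts outcomes in a pregnancy table and converts to percentages,
#' optionally within subgroups of a covariate.
#'
#' @param pregnancies Data frame with an `outcome` column (and the subgroup
#'   variable when `by` is given).
#' @param by Optional covariate name; one distribution per category.
#' @param weight Optional name of a weight column for weighted shares.
#' @return An [outcome_distribution()], or a named list of them when `by` is
#'   given (empty subgroups omitted with a warning).
#' @export
tabulate_outcomes <- function(pregnancies, by = NULL, weight = NULL) {
  if (!nrow(pregnancies)) stop("empty pregnancy table", call. = FALSE)
  if (!"outcome" %in% names(pregnancies))
    stop("`pregnancies` must contain an `outcome` column", call. = FALSE)
  tab_one <- function(df) {
    w <- if (is.null(weight)) rep(1, nrow(df)) else df[[weight]]
    agg <- tapply(w, as.character(df$outcome), sum)
    shares <- 100 * agg / sum(agg)
    outcome_distribution(setNames(as.numeric(shares), names(agg)),
                         total_pregnancies = nrow(df))
  }
  if (is.null(by)) return(tab_one(pregnancies))
  if (!by %in% names(pregnancies))
    stop(sprintf("subgroup variable `%s` not found", by), call. = FALSE)
  out <- list()
  for (lv in sort(unique(as.character(pregnancies[[by]])), method = "radix")) {
    df <- pregnancies[pregnancies[[by]] == lv, , drop = FALSE]
    if (!nrow(df)) {
      warning(sprintf("empty subgroup `%s` omitted", lv), call. = FALSE)
      next
    }
    out[[lv]] <- tab_one(df)
  }
  out
}

#' Write a correction table in the reported / rate / corrected layout
#'
#' @param reported An [outcome_distribution()].
#' @param rates Named rate vector in percent (see [correct_distribution()]).
#' @param path CSV output path.
#' @return The corrected [outcome_distribution()], invisibly.
#' @export
write_correction_table <- function(reported, rates, path) {
  corrected <- correct_distribution(reported, rates)
  labels <- names(reported$shares)
  full <- setNames(rep(100, length(labels)), labels)
  full[names(rates)] <- rates
  df <- data.frame(outcome = labels,
                   reported_share = round(reported$shares, 1),
                   reporting_rate = full,
                   corrected_share = round(corrected$shares, 1))
  write.csv(df, path, row.names = FALSE)
  invisible(corrected)
}
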