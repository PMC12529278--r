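#' Configure an end-to-end analysis run
#'
#' Bundles everything [run_pipeline()] needs: where to write outputs, which
#' stages to run, the simulation configuration (or paths to existing input
#' tables), the BT-ZIP candidate specifications, and the risk-model
#' specification. A single global seed is fanned out deterministically to the
#' stages as `seed + 1000 * stage_index` (stage order: simulate,
#' fit-reporting, select-model, correct, fit-risk), so any stage can be rerun
#' in isolation and reproduce its part of a full run.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param stages Stages to run, a subset of `c("simulate", "fit-reporting",
#'   "select-model", "correct", "fit-risk")`.
#' @param sim A [sim_config()]; default [fecond_like_preset()]. Ignored when
#'   both input paths are supplied and "simulate" is not requested.
#' @param respondents_path,pregnancies_path Optional existing input CSVs used
#'   instead of simulation output.
#' @param candidates A [candidate_set()] for the reporting model; the default
#'   pairs the preset's exclusion-restriction specification with simpler
#'   alternatives.
#' @param mnl An [mnl_spec()] for the risk model (kept deliberately small by
#'   default; raise `iter`/`chains` for production runs).
#' @param rates Named reporting-rate vector (percent) for the correction
#'   stage; default: the fitted average miscarriage reporting rate from the
#'   fit-reporting stage applied to the miscarriage share, with other
#'   outcomes assumed fully reported.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "fit-reporting",
                                       "select-model", "correct", "fit-risk"),
                            sim = fecond_like_preset(),
                            respondents_path = NULL,
                            pregnancies_path = NULL,
                            candidates = NULL,
                            mnl = mnl_spec(
                              c("age_group_at_start", "prior_miscarriages",
                                "education"),
                              chains = 2, iter = 1500, warmup = 750),
                            rates = NULL) {
  all_stages <- c("simulate", "fit-reporting", "select-model", "correct",
                  "fit-risk")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(candidates)) {
    candidates <- candidate_set(
      full = btzip_spec(
        count_covariates = c("education", "parity_survey"),
        zero_covariates = "infertility_treatment",
        report_covariates = c("education", "income", "health", "marital"),
        label = "full"),
      no_income = btzip_spec(
        count_covariates = c("education", "parity_survey"),
        zero_covariates = "infertility_treatment",
        report_covariates = c("education", "health", "marital"),
        label = "no_income")
    )
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, sim = sim,
                 respondents_path = respondents_path,
                 pregnancies_path = pregnancies_path,
                 candidates = candidates, mnl = mnl, rates = rates),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  all_stages <- c("simulate", "fit-reporting", "select-model", "correct",
                  "fit-risk")
  (seed + 1000L * match(stage, all_stages)) %% .Machine$integer.max
}

#' Run the two-part analysis pipeline
#'
#' Executes, as toggled in the config: data simulation (or reading of
#' existing tables), BT-ZIP reporting-rate estimation, AIC/BIC model
#' selection across candidates, reporting-rate correction of the outcome
#' distribution, and the multilevel multinomial risk model. Each stage writes
#' its tables under `out_dir`; a machine-readable run report (seed, package
#' version, per-stage row counts and exclusion tallies) is written as
#' `run_report.json` and returned. A stage failure halts the run with the
#' stage named; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit progress messages (default `TRUE`).
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$respondents_path, config$pregnancies_path))
    if (!is.null(p) && !file.exists(p))
      stop("configured input path does not exist: ", p, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list(package_version = as.character(utils::packageVersion("pregreport")),
                 r_version = R.version.string,
                 seed = config$seed, stages = list())
  fail <- function(stage, e)
    stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  respondents <- NULL
  pregnancies <- NULL
  reporting_fit <- NULL

  if ("simulate" %in% config$stages) {
    say("stage simulate")
    tryCatch({
      sim <- config$sim
      sim$seed <- stage_seed(config$seed, "simulate")
      respondents <- simulate_respondents(sim)
      pregnancies <- simulate_pregnancies(sim)
      write_respondents(respondents, file.path(config$out_dir, "respondents.csv"))
      write_pregnancies(pregnancies, file.path(config$out_dir, "pregnancies.csv"))
      report$stages$simulate <- list(
        n_respondents = nrow(respondents), n_pregnancies = nrow(pregnancies))
    }, error = function(e) fail("simulate", e))
  } else {
    if (!is.null(config$respondents_path))
      respondents <- read_respondents(config$respondents_path)
    if (!is.null(config$pregnancies_path))
      pregnancies <- read_pregnancies(config$pregnancies_path)
  }

  if ("fit-reporting" %in% config$stages) {
    say("stage fit-reporting")
    tryCatch({
      if (is.null(respondents)) stop("no respondent data available")
      spec1 <- config$candidates[[1]]
      reporting_fit <- btzip_fit(
        respondents, spec1,
        control = list(start_seed = stage_seed(config$seed, "fit-reporting")))
      rates <- average_reporting_rate(reporting_fit, respondents,
                                      by = "education")
      write_btzip_fit(reporting_fit, file.path(config$out_dir, "reporting_fit.json"))
      write.csv(rates, file.path(config$out_dir, "reporting_rates.csv"),
                row.names = FALSE)
      report$stages$fit_reporting <- list(
        n_obs = reporting_fit$n_obs, n_dropped = reporting_fit$n_dropped,
        converged = reporting_fit$converged,
        avg_reporting_rate = rates$rate[1])
    }, error = function(e) fail("fit-reporting", e))
  }

  if ("select-model" %in% config$stages) {
    say("stage select-model")
    tryCatch({
      if (is.null(respondents)) stop("no respondent data available")
      fits <- fit_candidates(
        respondents, config$candidates,
        control = list(start_seed = stage_seed(config$seed, "select-model")))
      tab <- robustness_table(fits, respondents)
      write.csv(tab, file.path(config$out_dir, "model_selection.csv"),
                row.names = FALSE)
      report$stages$select_model <- list(
        n_candidates = length(config$candidates),
        n_converged = sum(tab$converged),
        best_bic = tab$label[tab$best_bic][1])
    }, error = function(e) fail("select-model", e))
  }

  if ("correct" %in% config$stages) {
    say("stage correct")
    tryCatch({
      if (is.null(pregnancies)) stop("no pregnancy data available")
      reported <- tabulate_outcomes(pregnancies)
      rates <- config$rates
      if (is.null(rates)) {
        if (is.null(reporting_fit))
          stop("no reporting rates configured and no fitted reporting model")
        avg <- average_reporting_rate(reporting_fit, respondents)$rate[1]
        rates <- c(miscarriage = avg)
      }
      corrected <- write_correction_table(
        reported, rates, file.path(config$out_dir, "corrected_outcomes.csv"))
      report$stages$correct <- list(
        total_pregnancies = reported$total_pregnancies,
        reported_shares = as.list(reported$shares),
        corrected_shares = as.list(corrected$shares))
    }, error = function(e) fail("correct", e))
  }

  if ("fit-risk" %in% config$stages) {
    say("stage fit-risk")
    tryCatch({
      if (is.null(pregnancies)) stop("no pregnancy data available")
      mnl <- config$mnl
      mnl$seed <- stage_seed(config$seed, "fit-risk")
      fit <- fit_risk_model(pregnancies, mnl)
      write.csv(fit$summary, file.path(config$out_dir, "risk_posterior.csv"),
                row.names = FALSE)
      report$stages$fit_risk <- list(
        n_pregnancies = nrow(fit$data),
        n_women = length(unique(fit$data$woman_id)),
        diag_ok = fit$diag_ok)
    }, error = function(e) fail("fit-risk", e))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("run report written to %s", file.path(config$out_dir, "run_report.json"))
  invisible(report)
}
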