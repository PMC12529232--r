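# End-to-end transport pipeline: per target year -- harmonize, stack,
# impute, fit selection model, weight, fit weighted effect, pool, report.

#' Analysis configuration for the transport pipeline
#'
#' @param covariates selection-model covariates.
#' @param strat_vars stratification adjustment variables for the outcome
#'   model.
#' @param m number of imputations (ignored under `complete_case`).
#' @param seed master seed.
#' @param imputation_method `"chained_equations"` or
#'   `"multivariate_normal"`.
#' @param prediction_mode `"marginal"` (integrate the school effect out of
#'   selection probabilities) or `"conditional"`.
#' @param normalize_weights rescale the stored weights to mean 1.
#' @param truncate_weights optional percentile pair for weight truncation.
#' @param complete_case drop records with missing analysis variables
#'   instead of imputing.
#' @param england_only restrict trial records to schools in England before
#'   analysis.
#' @param nAGQ integration points for all multilevel fits (0 is faster).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(covariates = covariate_names(),
                            strat_vars = stratification_names(prefixed = TRUE),
                            m = 20L, seed = 1L,
                            imputation_method = "chained_equations",
                            prediction_mode = "marginal",
                            normalize_weights = FALSE,
                            truncate_weights = NULL,
                            complete_case = FALSE,
                            england_only = FALSE,
                            nAGQ = 1L) {
  if (!complete_case && m < 2) stop("m must be >= 2 unless complete_case")
  structure(list(
    covariates = covariates, strat_vars = strat_vars, m = as.integer(m),
    seed = as.integer(seed), imputation_method = imputation_method,
    prediction_mode = prediction_mode,
    normalize_weights = normalize_weights,
    truncate_weights = truncate_weights,
    complete_case = isTRUE(complete_case),
    england_only = isTRUE(england_only),
    nAGQ = as.integer(nAGQ)
  ), class = "analysis_config")
}

log_stage <- function(log, stage, n_in, n_out, note = "") {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note, stringsAsFactors = FALSE))
}

analysis_complete_cases <- function(records, config, with_outcome) {
  vars <- config$covariates
  if (with_outcome) vars <- c(vars, "outcome_weekly", "arm")
  records[stats::complete.cases(records[vars]), , drop = FALSE]
}

# One year's transported estimate on already-completed (no missing) data.
transport_one <- function(trial, target, year, config) {
  stacked <- stack_datasets(trial, target, year)
  sel <- fit_selection_model(stacked, config$covariates, nAGQ = config$nAGQ)
  keep <- transportable_mask(sel, trial)
  trial_used <- trial[keep, , drop = FALSE]
  p <- predict_selection_prob(sel, trial_used, mode = config$prediction_mode)
  ws <- inverse_odds_weights(p, normalize = config$normalize_weights,
                             truncate = config$truncate_weights)
  pos <- positivity_report(ws, stacked, config$covariates)
  est <- fit_transported_effect(trial_used, ws, config$strat_vars,
                                nAGQ = config$nAGQ, year = as.integer(year))
  list(estimate = est, weights = ws, positivity = pos, selection = sel,
       n_trial_excluded = sum(!keep))
}

#' Run the full transport analysis
#'
#' For each target year: harmonize and stack the trial with that year's
#' survey, multiply impute missing values (trial and survey separately),
#' fit the selection model and compute inverse-odds weights within each
#' completed dataset, fit the weighted multilevel outcome model, pool the
#' log odds ratios across imputations with Rubin's rules, and compute the
#' confidence interval ratio.  The unweighted trial-population estimate is
#' reported alongside.  A failure in one year is recorded as a structured
#' error and the remaining years still run.
#'
#' @param trial harmonized trial records, a data.frame or a CSV path.
#' @param surveys named list (names = years) of harmonized survey records
#'   or CSV paths.
#' @param config an [analysis_config()].
#' @return an object of class `transport_report`: list with `trial_estimate`,
#'   `year_estimates` (one entry per year: pooled `effect_estimate` plus
#'   diagnostics), `errors`, `log`, `config` and `seed`.
#' @export
run_transport <- function(trial, surveys, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  load_tab <- function(x) if (is.character(x)) read_participants(x) else
    harmonize_records(as.data.frame(x))
  trial <- load_tab(trial)
  surveys <- lapply(surveys, load_tab)
  if (is.null(names(surveys)) || any(!nzchar(names(surveys)))) {
    names(surveys) <- vapply(surveys, function(s) as.character(s$year[1]), "")
  }
  log <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    note = character(), stringsAsFactors = FALSE)
  log <- log_stage(log, "load-trial", nrow(trial), nrow(trial))
  if (config$england_only) {
    n0 <- nrow(trial)
    trial <- trial[trial$strat_country == "england", , drop = FALSE]
    log <- log_stage(log, "england-only-filter", n0, nrow(trial))
  }

  # trial-population (unweighted) estimate
  trial_est <- tryCatch({
    tr_cc <- analysis_complete_cases(trial, config, with_outcome = TRUE)
    if (nrow(tr_cc) == nrow(trial) || config$complete_case) {
      est <- fit_trial_effect(tr_cc, config$strat_vars, nAGQ = config$nAGQ)
      est$n_imputations <- NA_integer_
      est
    } else {
      imp <- impute(trial, m = config$m,
                    seed = substream_seed(config$seed, "impute-trial-only"),
                    method = config$imputation_method)
      fits <- lapply(imp$completed_datasets, fit_trial_effect,
                     strat_vars = config$strat_vars, nAGQ = config$nAGQ)
      pool_effect(fits, weighted = FALSE, year = NA_integer_)
    }
  }, error = function(e) structure(list(message = conditionMessage(e)),
                                   class = "transport_error"))
  log <- log_stage(log, "trial-estimate", nrow(trial), nrow(trial))

  year_out <- list()
  errors <- list()
  for (y in names(surveys)) {
    res <- tryCatch({
      target <- surveys[[y]]
      lg_n <- nrow(target)
      if (config$complete_case) {
        tr <- analysis_complete_cases(trial, config, with_outcome = TRUE)
        tg <- analysis_complete_cases(target, config, with_outcome = FALSE)
        one <- transport_one(tr, tg, y, config)
        est <- one$estimate
        est$n_imputations <- NA_integer_
        est$mcse <- NA_real_
        list(estimate = est, ess = one$weights$ess,
             positivity = one$positivity,
             n_trial_used = nrow(tr), n_target_used = nrow(tg),
             mc_error = NULL)
      } else {
        need_imp <- anyNA(trial[c(config$covariates, "outcome_weekly")]) ||
          anyNA(target[config$covariates])
        if (!need_imp) {
          one <- transport_one(trial, target, y, config)
          est <- one$estimate
          est$n_imputations <- NA_integer_
          est$mcse <- NA_real_
          list(estimate = est, ess = one$weights$ess,
               positivity = one$positivity,
               n_trial_used = nrow(trial), n_target_used = nrow(target),
               mc_error = NULL)
        } else {
          imp_tr <- impute(trial, m = config$m,
                           seed = substream_seed(config$seed, paste0("impute-trial-", y)),
                           method = config$imputation_method)
          imp_tg <- impute(target, variables = config$covariates, m = config$m,
                           seed = substream_seed(config$seed, paste0("impute-target-", y)),
                           method = config$imputation_method)
          ones <- lapply(seq_len(config$m), function(j) {
            transport_one(imp_tr$completed_datasets[[j]],
                          imp_tg$completed_datasets[[j]], y, config)
          })
          pooled <- pool_effect(lapply(ones, `[[`, "estimate"),
                                weighted = TRUE, year = as.integer(y))
          list(estimate = pooled,
               ess = mean(vapply(ones, function(o) o$weights$ess, 0)),
               positivity = ones[[1]]$positivity,
               n_trial_used = nrow(trial), n_target_used = nrow(target),
               mc_error = attr(pooled, "mc_error"))
        }
      }
    }, error = function(e) structure(list(year = y,
                                          message = conditionMessage(e)),
                                     class = "transport_error"))
    if (inherits(res, "transport_error")) {
      errors[[y]] <- res
      log <- log_stage(log, paste0("year-", y), nrow(surveys[[y]]), 0L,
                       note = res$message)
    } else {
      year_out[[y]] <- res
      log <- log_stage(log, paste0("year-", y), nrow(surveys[[y]]),
                       res$n_target_used)
    }
  }
  structure(list(
    trial_estimate = trial_est,
    year_estimates = year_out,
    errors = errors,
    log = log,
    config = config,
    seed = config$seed
  ), class = "transport_report")
}

# Pool a list of effect_estimates across imputations via Rubin's rules on
# the log-OR scale; carries the Monte Carlo error check as an attribute.
pool_effect <- function(fits, weighted, year) {
  q <- vapply(fits, function(f) f$log_or, 0)
  v <- vapply(fits, function(f) f$se^2, 0)
  pl <- pool_rubin(q, v)
  est <- new_effect_estimate(
    log_or = pl$qbar, se = sqrt(pl$T),
    n = fits[[1]]$n, n_schools = fits[[1]]$n_schools,
    weighted = weighted, year = year, df = pl$df,
    extra = list(n_imputations = pl$m, mcse = pl$mcse,
                 within_var = pl$W, between_var = pl$B)
  )
  attr(est, "mc_error") <- monte_carlo_error_check(pl)
  est
}

#' @export
print.transport_report <- function(x, ...) {
  cat("Transport analysis report\n")
  if (inherits(x$trial_estimate, "transport_error")) {
    cat("  trial estimate FAILED:", x$trial_estimate$message, "\n")
  } else {
    cat("  "); print(x$trial_estimate)
  }
  for (y in names(x$year_estimates)) {
    cat("  "); print(x$year_estimates[[y]]$estimate)
  }
  for (y in names(x$errors)) {
    cat(sprintf("  year %s FAILED: %s\n", y, x$errors[[y]]$message))
  }
  invisible(x)
}

#' Forest table / JSON serialization of a transport report
#'
#' @param report a `transport_report`.
#' @param dir output directory; created if needed.
#' @return (invisibly) the paths written: `report.json` and
#'   `forest_table.csv`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "transport_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ests <- c(
    if (!inherits(report$trial_estimate, "transport_error"))
      list(report$trial_estimate),
    lapply(report$year_estimates, `[[`, "estimate")
  )
  ft <- forest_table(ests)
  csv_path <- file.path(dir, "forest_table.csv")
  utils::write.csv(ft, csv_path, row.names = FALSE)
  to_json <- function(e) {
    e$model <- NULL
    e[!vapply(e, is.function, TRUE)]
  }
  payload <- list(
    seed = report$seed,
    config = unclass(report$config),
    trial_estimate = if (!inherits(report$trial_estimate, "transport_error"))
      to_json(unclass(report$trial_estimate)) else
        list(error = report$trial_estimate$message),
    years = lapply(report$year_estimates, function(yr) {
      list(estimate = to_json(unclass(yr$estimate)),
           ess = yr$ess,
           positivity_ok = yr$positivity$ok,
           flagged_cells = yr$positivity$flagged_cells,
           n_trial_used = yr$n_trial_used,
           n_target_used = yr$n_target_used,
           mc_error = yr$mc_error)
    }),
    errors = lapply(report$errors, function(e) e$message),
    log = report$log
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Write the default synthetic dataset bundle
#'
#' Generates the calibrated default trial and all five survey waves at their
#' published sample sizes (8756 trial records; 3958, 3377, 3145, 4874 and
#' 3587 survey records) and writes them as CSVs plus the generator
#' configuration as YAML.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @param scale divisor for a reduced-size bundle (e.g. 10 for a small test
#'   bundle with proportional counts).
#' @return named character vector of the files written.
#' @export
make_fixture_bundle <- function(out_dir, seed = 1L, scale = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- make_default_config(seed = seed)
  if (scale != 1) cfg <- scale_config(cfg, scale)
  paths <- c(config = file.path(out_dir, "config.yaml"))
  write_config(cfg, paths[["config"]])
  trial <- generate_trial(cfg, seed = seed)
  paths["trial"] <- file.path(out_dir, "trial.csv")
  write_participants(trial, paths[["trial"]])
  for (y in names(cfg$surveys)) {
    sv <- generate_survey(cfg, y, seed = seed)
    paths[paste0("survey_", y)] <- file.path(out_dir, paste0("survey_", y, ".csv"))
    write_participants(sv, paths[[paste0("survey_", y)]])
  }
  paths
}
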