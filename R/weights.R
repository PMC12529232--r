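# Selection model for trial membership and inverse-odds-of-selection
# weights, with positivity diagnostics.

#' Fit the multilevel selection model
#'
#' Fits a school random-intercept logistic regression of the selection
#' indicator `S` (1 = trial, 0 = target) on the harmonized covariates, on a
#' stacked trial + survey dataset.  Covariates enter as full categorical
#' indicator sets with the first schema level as reference.  Covariate
#' levels observed only in the target population are a positivity violation
#' and an error; levels observed only in the trial have true inverse
#' selection odds of zero, so those records are excluded from the fit with
#' a warning (see [transportable_mask()]) instead of silently driving a
#' separated coefficient.
#'
#' @param stacked a `stacked_data` object from [stack_datasets()], complete
#'   on the selection covariates (impute upstream).
#' @param covariates character vector of covariate names (default: all
#'   harmonized covariates, see [covariate_names()]).
#' @param random_intercept `"auto"` (default), `"always"` or `"never"`.
#'   Because the trial and target schools are disjoint, the selection
#'   indicator is constant within every school; a school random intercept is
#'   then not identified separately from selection itself, its estimated SD
#'   diverges, and the covariate-specific selection odds are destroyed.
#'   Under `"auto"` the school term is therefore dropped (with a message)
#'   exactly when `S` is school-constant, and kept whenever selection varies
#'   within clusters; `"always"`/`"never"` force either choice.
#' @param nAGQ integration points passed to [lme4::glmer()] (0 gives a
#'   faster, slightly cruder fit).
#' @return an object of class `selection_fit`: list with `model` (merMod or
#'   glm), `coefficients`, `intercept`, `random_intercept_sd`, `converged`,
#'   `n_used` and `covariates`.
#' @export
fit_selection_model <- function(stacked, covariates = covariate_names(),
                                random_intercept = c("auto", "always", "never"),
                                nAGQ = 1L) {
  stopifnot(inherits(stacked, "stacked_data"))
  random_intercept <- match.arg(random_intercept)
  dat <- as.data.frame(stacked)
  cc <- stats::complete.cases(dat[covariates])
  if (!all(cc)) {
    stop("stacked dataset has missing values on selection covariates; ",
         "impute or restrict to complete cases first")
  }
  if (length(unique(dat$school_id[dat$S == 1])) < 2 ||
      length(unique(dat$school_id[dat$S == 0])) < 2) {
    stop("need at least 2 schools per source")
  }
  drop_rows <- check_positivity_levels(dat, covariates)
  n_excluded <- sum(drop_rows)
  dat <- dat[!drop_rows, , drop = FALSE]
  dat <- as_model_factors(dat, covariates)
  for (v in covariates) dat[[v]] <- droplevels(dat[[v]])
  single <- covariates[vapply(dat[covariates], nlevels, 1L) < 2L]
  if (length(single)) {
    stop("covariate(s) with a single level in the stacked data: ",
         paste(single, collapse = ", "))
  }
  levels_used <- lapply(dat[covariates], levels)
  dat$school_id <- factor(dat$school_id)
  s_constant <- all(tapply(dat$S, dat$school_id, function(s) length(unique(s))) == 1L)
  use_re <- switch(random_intercept,
                   always = TRUE, never = FALSE, auto = !s_constant)
  if (random_intercept == "auto" && s_constant) {
    message("selection indicator is constant within schools; ",
            "school random intercept dropped (see ?fit_selection_model)")
  }
  if (use_re) {
    form <- stats::reformulate(c(covariates, "(1 | school_id)"), response = "S")
    fit <- suppressMessages(lme4::glmer(
      form, data = dat, family = stats::binomial(), nAGQ = nAGQ,
      control = lme4::glmerControl(check.conv.grad =
        lme4::.makeCC("warning", tol = 5e-3, relTol = NULL))
    ))
    conv <- is.null(fit@optinfo$conv$lme4$code) ||
      fit@optinfo$conv$lme4$code >= 0
    beta <- lme4::fixef(fit)
    sd_u <- sqrt(unname(lme4::VarCorr(fit)$school_id[1, 1]))
  } else {
    form <- stats::reformulate(covariates, response = "S")
    fit <- stats::glm(form, data = dat, family = stats::binomial())
    conv <- fit$converged
    beta <- stats::coef(fit)
    aliased <- names(beta)[is.na(beta)]
    if (length(aliased)) {
      message("aliased selection coefficients dropped: ",
              paste(aliased, collapse = ", "))
      beta <- beta[!is.na(beta)]
    }
    sd_u <- 0
  }
  structure(list(
    model = fit,
    coefficients = beta[names(beta) != "(Intercept)"],
    intercept = unname(beta[["(Intercept)"]]),
    random_intercept_sd = sd_u,
    converged = conv,
    n_used = nrow(dat),
    n_excluded = n_excluded,
    covariates = covariates,
    levels_used = levels_used,
    beta = beta
  ), class = "selection_fit")
}

# Positivity screening of covariate levels against the selection indicator.
# A level observed only in the TARGET population violates population
# positivity (no comparable trial participants exist) and is an error.  A
# level observed only in the TRIAL is not an identification problem for
# transport -- such participants simply resemble no target member and their
# true inverse selection odds is zero -- but it separates the selection
# model, so those rows are flagged for exclusion (with a warning) rather
# than silently driving a divergent coefficient.
check_positivity_levels <- function(dat, covariates) {
  drop_rows <- rep(FALSE, nrow(dat))
  for (v in covariates) {
    tab <- table(factor(dat[[v]]), dat$S)
    target_only <- rownames(tab)[tab[, "1"] == 0]
    if (length(target_only)) {
      stop("positivity violation: level(s) ", paste(target_only, collapse = ", "),
           " of ", v, " observed only in the target population")
    }
    trial_only <- rownames(tab)[tab[, "0"] == 0]
    if (length(trial_only)) {
      hit <- dat[[v]] %in% trial_only
      warning("level(s) ", paste(trial_only, collapse = ", "), " of ", v,
              " absent from the target population; ", sum(hit),
              " trial record(s) excluded from the selection fit ",
              "(their inverse selection odds is zero)")
      drop_rows <- drop_rows | hit
    }
  }
  drop_rows
}

#' Which records fall inside the fitted selection model's support
#'
#' `TRUE` for records whose covariate levels were all observed in both
#' populations at fit time; records with trial-only levels (true inverse
#' selection odds zero) get `FALSE` and should be excluded from the
#' weighted analysis.
#'
#' @param fit a `selection_fit`.
#' @param records harmonized participant records.
#' @return logical vector along the rows of `records`.
#' @export
transportable_mask <- function(fit, records) {
  stopifnot(inherits(fit, "selection_fit"))
  keep <- rep(TRUE, nrow(records))
  for (v in fit$covariates) {
    keep <- keep & as.character(records[[v]]) %in% fit$levels_used[[v]]
  }
  keep
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("Selection model: %d records, school SD %.3f, %s\n",
              x$n_used, x$random_intercept_sd,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Predicted probability of selection into the trial
#'
#' Computes each record's probability of being a trial (rather than target)
#' participant under a fitted selection model.  By default the school random
#' intercept is integrated out numerically (Gauss-Hermite quadrature), since
#' the weighting step must evaluate trial records as exchangeable members of
#' either population and target schools carry no estimated trial effect.
#' Conditional prediction (using a school's estimated random effect) is
#' available for sensitivity analyses.
#'
#' @param fit a `selection_fit`.
#' @param records harmonized participant data.frame.
#' @param mode `"marginal"` (default) or `"conditional"`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_selection_prob <- function(fit, records, mode = c("marginal", "conditional")) {
  stopifnot(inherits(fit, "selection_fit"))
  if (!fit$converged) stop("selection model did not converge; refusing to predict")
  mode <- match.arg(mode)
  dat <- as.data.frame(records)
  for (v in fit$covariates) {
    x <- as.character(dat[[v]])
    unseen <- !is.na(x) & !x %in% fit$levels_used[[v]]
    if (any(unseen)) {
      stop("covariate level unseen in fit: ", v, " = ",
           paste(unique(x[unseen]), collapse = ", "))
    }
    dat[[v]] <- factor(x, levels = fit$levels_used[[v]])
  }
  mm <- stats::model.matrix(stats::reformulate(fit$covariates), dat)
  beta <- fit$beta
  eta <- as.vector(mm[, names(beta), drop = FALSE] %*% beta)
  if (mode == "marginal" || fit$random_intercept_sd == 0) {
    marginal_expit(eta, fit$random_intercept_sd)
  } else {
    re <- lme4::ranef(fit$model)$school_id
    u <- stats::setNames(re[, 1], rownames(re))
    us <- u[as.character(records$school_id)]
    us[is.na(us)] <- 0  # schools unseen at fit time get the population mode
    expit(eta + unname(us))
  }
}

#' Inverse-odds-of-selection weights for trial records
#'
#' Trial record `i` with selection probability `p_i` receives weight
#' `w_i = (1 - p_i) / p_i`, the inverse of its odds of being in the trial
#' rather than the target population; the weighted trial then resembles the
#' target.  Weights are left unnormalized by default (point estimates of
#' weighted logistic fits are invariant to weight scale); `normalize = TRUE`
#' rescales them to mean one.  Optional symmetric percentile truncation is
#' available for extreme-weight diagnostics and is off by default.
#'
#' @param selection_probs probabilities for the trial records, strictly
#'   inside (0, 1).
#' @param normalize rescale weights to mean 1.
#' @param truncate optional length-2 probability pair, e.g. `c(0.01, 0.99)`,
#'   at which to winsorize the weights.
#' @return an object of class `weight_set`: list with `weights`,
#'   `selection_probs`, `ess`, `min_p`, `max_p`, `truncation`, `normalized`.
#' @export
#' @examples
#' inverse_odds_weights(c(0.5, 0.2))$weights  # 1 and 4
inverse_odds_weights <- function(selection_probs, normalize = FALSE,
                                 truncate = NULL) {
  p <- as.numeric(selection_probs)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("positivity failure: selection probabilities must lie strictly in (0, 1)")
  }
  w <- (1 - p) / p
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2, truncate[1] < truncate[2])
    q <- stats::quantile(w, truncate, names = FALSE)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  if (normalize) w <- w / mean(w)
  structure(list(
    weights = w,
    selection_probs = p,
    ess = effective_sample_size(w),
    min_p = min(p), max_p = max(p),
    truncation = truncate,
    normalized = normalize
  ), class = "weight_set")
}

#' Effective sample size of a weight vector
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally weighted observations
#' carrying the same information.  Always at most `length(w)`, with equality
#' iff all weights are equal.
#'
#' @param w positive weights.
#' @return numeric scalar.
#' @export
effective_sample_size <- function(w) sum(w)^2 / sum(w^2)

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Inverse-odds weights: n %d, ESS %.1f, p in [%.4f, %.4f]\n",
              length(x$weights), x$ess, x$min_p, x$max_p))
  print(summary(x$weights))
  invisible(x)
}

#' Positivity report for a weighted transport analysis
#'
#' Summarises the weight distribution (ESS, quantiles, probability range)
#' and scans every selection covariate for levels that occur in the target
#' population but are absent from either trial arm -- a violation of
#' population positivity, under which the transported effect for those
#' profiles is extrapolation.
#'
#' @param weightset a `weight_set` for the trial records of `stacked`.
#' @param stacked the `stacked_data` the weights were computed for.
#' @param covariates covariates to scan.
#' @return an object of class `positivity_report`: list with `ess`,
#'   `n_trial`, `weight_quantiles`, `p_range`, `flagged_cells` (data.frame)
#'   and `ok`.
#' @export
positivity_report <- function(weightset, stacked,
                              covariates = covariate_names()) {
  stopifnot(inherits(weightset, "weight_set"), inherits(stacked, "stacked_data"))
  dat <- as.data.frame(stacked)
  trial <- dat[dat$S == 1, , drop = FALSE]
  target <- dat[dat$S == 0, , drop = FALSE]
  flagged <- list()
  for (v in covariates) {
    lv_target <- unique(stats::na.omit(as.character(target[[v]])))
    for (l in lv_target) {
      for (a in c("control", "intervention")) {
        n_arm <- sum(trial$arm == a & as.character(trial[[v]]) == l, na.rm = TRUE)
        if (n_arm == 0) {
          flagged[[length(flagged) + 1L]] <- data.frame(
            covariate = v, level = l, arm = a,
            n_target = sum(as.character(target[[v]]) == l, na.rm = TRUE),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(covariate = character(), level = character(),
               arm = character(), n_target = integer())
  structure(list(
    ess = weightset$ess,
    n_trial = length(weightset$weights),
    weight_quantiles = stats::quantile(weightset$weights,
                                       c(0, 0.01, 0.25, 0.5, 0.75, 0.99, 1)),
    p_range = c(weightset$min_p, weightset$max_p),
    flagged_cells = flagged,
    ok = nrow(flagged) == 0
  ), class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat(sprintf("Positivity report: ESS %.1f of %d trial records; p in [%.4f, %.4f]\n",
              x$ess, x$n_trial, x$p_range[1], x$p_range[2]))
  if (x$ok) {
    cat("  no target covariate cells empty in a trial arm\n")
  } else {
    cat("  FLAGGED cells (present in target, absent in a trial arm):\n")
    print(x$flagged_cells)
  }
  invisible(x)
}
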