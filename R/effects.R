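# Intervention-effect estimation: unweighted and inverse-odds-weighted
# school random-intercept logistic fits, cluster-robust variance for the
# weighted fit, and the confidence interval ratio precision metric.

new_effect_estimate <- function(log_or, se, n, n_schools, weighted,
                                year = NA_integer_, df = Inf, extra = list()) {
  if (!is.finite(log_or) || !is.finite(se) || se < 0 || se > 50) {
    stop("degenerate effect fit (log-OR ", format(log_or), ", SE ",
         format(se), "): the model carries no usable information")
  }
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  ci_low <- exp(log_or - crit * se)
  ci_high <- exp(log_or + crit * se)
  structure(c(list(
    log_or = log_or, se = se, or_ = exp(log_or),
    ci_low = ci_low, ci_high = ci_high,
    ci_ratio = ci_ratio(ci_low, ci_high),
    n = n, n_schools = n_schools, weighted = weighted,
    year = year, df = df
  ), extra), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (is.na(x$year)) "trial" else paste("year", x$year)
  cat(sprintf("%s %s effect: OR %.3f (95%% CI %.3f-%.3f), CI ratio %.2f, n = %d in %d schools\n",
              if (x$weighted) "Transported" else "Trial-population", lab,
              x$or_, x$ci_low, x$ci_high, x$ci_ratio, x$n, x$n_schools))
  invisible(x)
}

#' Confidence interval ratio
#'
#' The ratio of the upper to the lower confidence limit: a scale-free
#' summary of the precision of a ratio estimate (1 = degenerate interval;
#' larger = less precise).
#'
#' @param ci_low,ci_high positive confidence limits, `ci_low <= ci_high`.
#' @return numeric scalar `ci_high / ci_low`.
#' @export
#' @examples
#' ci_ratio(0.72, 1.13)
ci_ratio <- function(ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) stop("confidence limits must be positive")
  if (any(ci_high < ci_low)) stop("ci_high must be >= ci_low")
  ci_high / ci_low
}

# Stratification variables usable as fixed effects: a level carried by fewer
# than two schools is confounded with a single school's random intercept, so
# that variable is dropped from the adjustment with a warning.
usable_strat_vars <- function(records, strat_vars) {
  keep <- character(0)
  for (v in strat_vars) {
    tab <- table(unique(records[, c("school_id", v)])[[v]])
    if (length(tab) < 2) next  # constant: nothing to adjust for
    if (any(tab < 2)) {
      warning("stratification variable ", v,
              " has a level with a single school; dropped from adjustment")
      next
    }
    # a level whose records carry no outcome variation separates the fit
    ev <- tapply(records$outcome_weekly, records[[v]], function(y)
      length(unique(y)))
    if (any(ev < 2)) {
      warning("stratification variable ", v,
              " has a level with a constant outcome; dropped from adjustment")
      next
    }
    keep <- c(keep, v)
  }
  # screen near-collinearity at school level: each kept variable must be
  # distinguishable from the design so far in at least ~2 schools, else its
  # coefficient is confounded with single school effects
  sch <- unique(records[c("school_id", keep)])
  basis <- matrix(1, nrow(sch), 1)
  keep2 <- character(0)
  for (v in keep) {
    x <- as.numeric(factor(sch[[v]])) - 1
    resid <- x - basis %*% qr.solve(basis, x)
    if (sum(resid^2) > 1.0) {
      keep2 <- c(keep2, v)
      basis <- cbind(basis, x)
    } else {
      warning("stratification variable ", v,
              " is school-collinear with the design; dropped from adjustment")
    }
  }
  keep2
}

prepare_outcome_data <- function(records, strat_vars) {
  dat <- as.data.frame(records)
  dat <- dat[!is.na(dat$outcome_weekly) & !is.na(dat$arm), , drop = FALSE]
  if (!nrow(dat)) stop("no records with outcome and arm")
  for (a in c("control", "intervention")) {
    ya <- dat$outcome_weekly[dat$arm == a]
    if (!length(ya)) stop("arm ", a, " has no records")
    if (length(unique(ya)) < 2) {
      stop("outcome is constant within arm ", a, ": no information on the effect")
    }
  }
  dat$arm <- factor(dat$arm, levels = c("control", "intervention"))
  dat$school_id <- factor(as.character(dat$school_id))
  strat_vars <- usable_strat_vars(dat, strat_vars)
  dat <- as_model_factors(dat, strat_vars)
  list(data = dat, strat_vars = strat_vars)
}

fit_outcome_glmm <- function(dat, strat_vars, weights = NULL, nAGQ = 1L) {
  multi_school <- nlevels(dat$school_id) >= 2
  rhs <- c("arm", strat_vars, if (multi_school) "(1 | school_id)")
  form <- stats::reformulate(rhs, response = "outcome_weekly")
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  if (multi_school) {
    fit <- suppressMessages(suppressWarnings(lme4::glmer(
      form, data = dat, family = stats::binomial(), weights = .w, nAGQ = nAGQ)))
  } else {
    fit <- suppressWarnings(stats::glm(form, data = dat,
                                       family = stats::quasibinomial(),
                                       weights = .w))
  }
  fit
}

#' Unweighted intervention effect in the trial population
#'
#' Fits a school random-intercept logistic regression of the weekly-smoking
#' outcome on study arm, adjusting for the school-level stratification
#' variables used in the randomization, and reports the exponentiated arm
#' coefficient with a Wald 95% confidence interval.
#'
#' @param records harmonized trial participant records with `outcome_weekly`
#'   and `arm` observed.
#' @param strat_vars stratification columns to adjust for (default: all six).
#' @param nAGQ integration points for [lme4::glmer()].
#' @return an `effect_estimate`.
#' @export
fit_trial_effect <- function(records,
                             strat_vars = stratification_names(prefixed = TRUE),
                             nAGQ = 1L) {
  prep <- prepare_outcome_data(records, strat_vars)
  fit <- fit_outcome_glmm(prep$data, prep$strat_vars, nAGQ = nAGQ)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  k <- "armintervention"
  new_effect_estimate(
    log_or = unname(b[[k]]),
    se = sqrt(V[k, k]),
    n = nrow(prep$data),
    n_schools = nlevels(prep$data$school_id),
    weighted = FALSE,
    extra = list(model = fit)
  )
}

#' Transported intervention effect under inverse-odds weights
#'
#' Fits the weighted analogue of [fit_trial_effect()] by weighted
#' pseudo-likelihood: the school random-intercept logistic model is fit with
#' each trial participant contributing their inverse-odds-of-selection
#' weight, and the variance of the arm coefficient is estimated with a
#' cluster-robust (school-level) sandwich, which is conservative with
#' respect to the estimation noise in the weights.  Weights are rescaled to
#' mean one before fitting by default, making the fit invariant to the
#' overall weight scale; `rescale_weights = FALSE` keeps the raw scale (so
#' integer weights reproduce a row-replicated fit exactly).
#'
#' @param records harmonized trial records.
#' @param weights a `weight_set` from [inverse_odds_weights()], or a bare
#'   numeric vector, aligned with `records` rows.
#' @param strat_vars stratification columns to adjust for.
#' @param rescale_weights rescale weights to mean 1 before fitting.
#' @param nAGQ integration points for [lme4::glmer()].
#' @param year optional target-population year recorded on the estimate.
#' @return an `effect_estimate` with `weighted = TRUE`.
#' @export
fit_transported_effect <- function(records, weights,
                                   strat_vars = stratification_names(prefixed = TRUE),
                                   rescale_weights = TRUE, nAGQ = 1L,
                                   year = NA_integer_) {
  w <- if (inherits(weights, "weight_set")) weights$weights else as.numeric(weights)
  if (length(w) != nrow(records)) {
    stop("weights and records are misaligned: ", length(w), " weights for ",
         nrow(records), " records")
  }
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  dat0 <- as.data.frame(records)
  dat0$.w_in <- w
  prep <- prepare_outcome_data(dat0, strat_vars)
  dat <- prep$data
  wfit <- dat$.w_in
  if (rescale_weights) wfit <- wfit / mean(wfit)
  fit <- fit_outcome_glmm(dat, prep$strat_vars, weights = wfit, nAGQ = nAGQ)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- cluster_sandwich_vcov(fit, dat, prep$strat_vars, wfit)
  k <- "armintervention"
  new_effect_estimate(
    log_or = unname(b[[k]]),
    se = sqrt(V[k, k]),
    n = nrow(dat),
    n_schools = nlevels(dat$school_id),
    weighted = TRUE,
    year = year,
    extra = list(model = fit, ess = effective_sample_size(wfit))
  )
}

# Cluster-robust sandwich covariance of the fixed effects of a (possibly
# weighted) random-intercept logistic fit.  Clusters are schools.  The meat
# is built from per-cluster scores of the integrated weighted log-likelihood
# with respect to the fixed effects, evaluated by adaptive Gauss-Hermite
# quadrature centred at each cluster's posterior mode of the random
# intercept; the bread is the model-based covariance.  For a single-level
# glm fit the scores are the usual per-observation weighted scores.
cluster_sandwich_vcov <- function(fit, dat, strat_vars, w, n_gh = 15L) {
  X <- stats::model.matrix(stats::reformulate(c("arm", strat_vars)), dat)
  y <- dat$outcome_weekly
  cl <- as.character(dat$school_id)
  if (inherits(fit, "merMod")) {
    beta <- lme4::fixef(fit)
    X <- X[, names(beta), drop = FALSE]
    eta0 <- as.vector(X %*% beta)
    sigma <- sqrt(lme4::VarCorr(fit)$school_id[1, 1])
    bread <- as.matrix(stats::vcov(fit))
  } else {
    beta <- stats::coef(fit)
    X <- X[, names(beta), drop = FALSE]
    eta0 <- as.vector(X %*% beta)
    sigma <- 0
    mu <- expit(eta0)
    A <- crossprod(X, X * (w * mu * (1 - mu)))
    bread <- solve(A)
  }
  clusters <- unique(cl)
  G <- length(clusters)
  p <- ncol(X)
  meat <- matrix(0, p, p)
  gh <- gauss_hermite_normal(n_gh)
  for (g in clusters) {
    idx <- which(cl == g)
    Xg <- X[idx, , drop = FALSE]
    yg <- y[idx]
    wg <- w[idx]
    eg <- eta0[idx]
    if (sigma < 1e-8) {
      score <- crossprod(Xg, wg * (yg - expit(eg)))
    } else {
      # adaptive GH: centre at the posterior mode of the school intercept
      f1 <- function(u) -u / sigma^2 + sum(wg * (yg - expit(eg + u)))
      f2 <- function(u) {
        pu <- expit(eg + u)
        -1 / sigma^2 - sum(wg * pu * (1 - pu))
      }
      u_hat <- 0
      for (it in 1:25) {
        step <- f1(u_hat) / f2(u_hat)
        u_hat <- u_hat - step
        if (abs(step) < 1e-10) break
      }
      tau <- 1 / sqrt(-f2(u_hat))
      uk <- u_hat + tau * gh$nodes
      logpost <- vapply(uk, function(u) {
        etau <- eg + u
        l1pe <- ifelse(etau > 30, etau, log1p(exp(etau)))
        -u^2 / (2 * sigma^2) + sum(wg * (yg * etau - l1pe))
      }, 0)
      # importance correction against the N(u_hat, tau^2) proposal implicit
      # in the normal-transformed nodes/weights
      logw <- log(gh$weights) + logpost + (uk - u_hat)^2 / (2 * tau^2)
      om <- exp(logw - max(logw))
      om <- om / sum(om)
      score <- matrix(0, p, 1)
      for (k in seq_along(uk)) {
        score <- score + om[k] * crossprod(Xg, wg * (yg - expit(eg + uk[k])))
      }
    }
    meat <- meat + tcrossprod(score)
  }
  meat <- meat * G / max(1, G - 1)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Forest table of effect estimates
#'
#' Flattens a list of `effect_estimate`s into a data.frame with one row per
#' analysis (year, OR, confidence limits, CI ratio, sample sizes), suitable
#' for a forest plot or CSV export.
#'
#' @param estimates list of `effect_estimate` objects.
#' @return data.frame.
#' @export
forest_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    data.frame(
      year = ifelse(is.na(e$year), NA_integer_, e$year),
      weighted = e$weighted,
      or_ = e$or_, ci_low = e$ci_low, ci_high = e$ci_high,
      ci_ratio = e$ci_ratio, log_or = e$log_or, se = e$se,
      n = e$n, n_schools = e$n_schools
    )
  })
  do.call(rbind, rows)
}
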