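# Missing data: MAR diagnostic, controlled amputation for testing, multiple
# imputation of the categorical schema variables, Rubin's-rules pooling and
# the Monte Carlo error check.

#' Missing-at-random plausibility diagnostic
#'
#' Fits a school random-intercept logistic regression of a binary
#' missingness indicator (1 = value missing) for one variable on the
#' observed covariates.  Covariates predicting missingness are compatible
#' with a missing-at-random mechanism given those covariates (as opposed to
#' missing completely at random); the assumption that missingness does not
#' additionally depend on the unobserved values themselves remains
#' untestable.
#'
#' @param records harmonized participant records.
#' @param variable the variable whose missingness is diagnosed.
#' @param covariates predictors (default: the other harmonized covariates).
#' @param nAGQ integration points for [lme4::glmer()].
#' @return list with `variable`, `n_missing`, `n`, and `coefficients`
#'   (data.frame of estimates, SEs, z and p values).
#' @export
missingness_diagnostic <- function(records, variable,
                                   covariates = setdiff(covariate_names(), variable),
                                   nAGQ = 1L) {
  dat <- as.data.frame(records)
  if (!variable %in% names(dat)) stop("unknown variable: ", variable)
  miss <- is.na(dat[[variable]])
  if (!any(miss)) stop("variable ", variable, " is fully observed: nothing to diagnose")
  if (all(miss)) stop("variable ", variable, " is fully missing")
  keep <- stats::complete.cases(dat[covariates])
  dat <- dat[keep, , drop = FALSE]
  dat$.miss <- as.integer(miss[keep])
  dat <- as_model_factors(dat, covariates)
  for (v in covariates) dat[[v]] <- droplevels(dat[[v]])
  covariates <- covariates[vapply(dat[covariates], function(f) nlevels(f) > 1, TRUE)]
  dat$school_id <- factor(dat$school_id)
  form <- stats::reformulate(c(covariates, "(1 | school_id)"), response = ".miss")
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = nAGQ)))
  sm <- summary(fit)$coefficients
  list(
    variable = variable,
    n_missing = sum(miss),
    n = length(miss),
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      z = sm[, 3], p = sm[, 4], row.names = NULL
    ),
    model = fit
  )
}

#' Impose missingness on a dataset (test harness)
#'
#' Amputation with a known mechanism, for recovery testing of the imputation
#' pipeline.  Each mechanism entry targets one variable and specifies a
#' marginal missingness `rate` and, for MAR mechanisms, per-level log-odds
#' shifts driven by *other*, observed variables; an empty `predictors` list
#' gives MCAR.  The mechanism intercept is solved so the realized expected
#' rate equals `rate`.  Mechanisms referencing the amputed variable itself
#' (MNAR) are rejected.
#'
#' @param records harmonized participant records.
#' @param mechanism named list: `variable = list(rate =, predictors = list(
#'   other_var = c(level = log_odds, ...)))`.
#' @param seed integer seed.
#' @return the records with NAs imposed; the original columns are kept in
#'   `attr(, "truth")` for recovery tests.
#' @export
#' @examples
#' cfg <- scale_config(make_default_config(), 40)
#' tr <- generate_trial(cfg, seed = 1)
#' amp <- amputate(tr, list(lesson_smoking = list(rate = 0.2)), seed = 2)
#' mean(is.na(amp$lesson_smoking))
amputate <- function(records, mechanism, seed = 1L) {
  dat <- as.data.frame(records)
  truth <- dat[names(mechanism)]
  with_seed(substream_seed(seed, "amputate"), {
    for (v in names(mechanism)) {
      spec <- mechanism[[v]]
      rate <- spec$rate %||% 0
      stopifnot(rate >= 0, rate <= 1)
      if (rate == 0) next
      preds <- spec$predictors %||% list()
      if (v %in% names(preds)) {
        stop("mechanism for ", v, " references its own value (MNAR not supported)")
      }
      lp <- rep(0, nrow(dat))
      for (pv in names(preds)) {
        if (any(is.na(dat[[pv]]))) {
          stop("MAR predictor ", pv, " must be fully observed")
        }
        shift <- preds[[pv]]
        lp <- lp + ifelse(as.character(dat[[pv]]) %in% names(shift),
                          shift[as.character(dat[[pv]])], 0)
      }
      alpha <- if (rate == 1) Inf else
        stats::uniroot(function(a) mean(expit(a + lp)) - rate,
                       c(-30, 30), tol = 1e-10)$root
      miss <- stats::runif(nrow(dat)) < expit(alpha + lp)
      dat[[v]][miss] <- NA
    }
    structure(dat, truth = truth)
  })
}

# One chained-equations conditional draw for a categorical variable:
# fit a (multinomial) logistic model of var on predictors over the observed
# rows, perturb the coefficients with a draw from their approximate
# sampling distribution, and sample the missing values from the implied
# category probabilities.
draw_conditional <- function(dat, v, predictors, miss_idx) {
  obs <- dat[-miss_idx, , drop = FALSE]
  lv <- levels(droplevels(factor(obs[[v]])))
  if (length(lv) < 2) {  # observed part degenerate: draw the single level
    return(rep(lv, length(miss_idx)))
  }
  form <- stats::reformulate(predictors, response = v)
  mf_all <- dat
  mf_all[[v]] <- factor(as.character(dat[[v]]), levels = lv)
  X <- stats::model.matrix(stats::reformulate(predictors), mf_all)
  Xobs <- X[-miss_idx, , drop = FALSE]
  Xmis <- X[miss_idx, , drop = FALSE]
  yobs <- mf_all[[v]][-miss_idx]
  if (length(lv) == 2) {
    fit <- suppressWarnings(stats::glm.fit(Xobs, as.integer(yobs) - 1L,
                                           family = stats::binomial()))
    beta <- fit$coefficients
    ok <- !is.na(beta)
    mu <- expit(as.vector(Xobs[, ok, drop = FALSE] %*% beta[ok]))
    info <- crossprod(Xobs[, ok, drop = FALSE],
                      Xobs[, ok, drop = FALSE] * pmax(mu * (1 - mu), 1e-8))
    Vc <- tryCatch(chol(solve(info)), error = function(e) NULL)
    bdraw <- beta[ok]
    if (!is.null(Vc)) bdraw <- bdraw + as.vector(t(Vc) %*% stats::rnorm(sum(ok)))
    p1 <- expit(as.vector(Xmis[, ok, drop = FALSE] %*% bdraw))
    ifelse(stats::runif(length(miss_idx)) < p1, lv[2], lv[1])
  } else {
    utils::capture.output(
      fit <- nnet::multinom(form, data = mf_all[-miss_idx, , drop = FALSE],
                            trace = FALSE, maxit = 200))
    cf <- stats::coef(fit)  # (K-1) x p
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    theta <- as.vector(t(cf))
    if (!is.null(vc)) {
      Vc <- tryCatch(chol(vc), error = function(e) NULL)
      if (!is.null(Vc)) theta <- theta + as.vector(t(Vc) %*% stats::rnorm(length(theta)))
    }
    B <- matrix(theta, nrow = nrow(cf), byrow = TRUE)
    eta <- Xmis[, colnames(cf), drop = FALSE] %*% t(B)
    pm <- cbind(1, exp(eta))
    pm <- pm / rowSums(pm)
    lv[apply(pm, 1L, function(p) sample.int(length(p), 1L, prob = p))]
  }
}

#' Multiple imputation of harmonized categorical variables
#'
#' Default method is chained equations tailored to the all-categorical
#' schema: each incomplete variable is imputed from a logistic (binary) or
#' multinomial (3+ levels) conditional model on the other analysis
#' variables, with parameter draws from the approximate posterior, iterated
#' for a fixed number of cycles.  The alternate `"multivariate_normal"`
#' method imputes on an indicator coding under an approximate joint normal
#' model (complete-case moments re-estimated on a bootstrap resample per
#' imputation, conditional draws, probabilistic rounding back to
#' categories).  Trial and survey datasets should be imputed separately.
#'
#' @param records harmonized participant records for ONE dataset.
#' @param variables variables to impute (default: the harmonized covariates,
#'   plus `outcome_weekly` when present and incomplete).
#' @param m number of imputations (>= 2).
#' @param seed integer seed; the same seed reproduces the imputation set.
#' @param method `"chained_equations"` (default) or `"multivariate_normal"`.
#' @param cycles chained-equation cycles per imputation.
#' @return an object of class `imputation_set`: list with
#'   `completed_datasets` (list of m data.frames without missing values on
#'   `variables`), `m`, `method`, `seed`, `variables`.
#' @export
impute <- function(records, variables = NULL, m = 20L, seed = 1L,
                   method = c("chained_equations", "multivariate_normal"),
                   cycles = 10L) {
  method <- match.arg(method)
  if (m < 2) stop("m must be at least 2")
  dat <- as.data.frame(records)
  if (is.null(variables)) {
    variables <- covariate_names()
    if ("outcome_weekly" %in% names(dat) && any(!is.na(dat$outcome_weekly))) {
      variables <- c(variables, "outcome_weekly")
    }
  }
  # outcome is all-NA on target records by design; never "impute" those
  target_rows <- if ("source" %in% names(dat)) dat$source == "target" else
    rep(FALSE, nrow(dat))
  miss_map <- lapply(variables, function(v) {
    idx <- which(is.na(dat[[v]]))
    if (v == "outcome_weekly") idx <- setdiff(idx, which(target_rows))
    idx
  })
  names(miss_map) <- variables
  to_fill <- variables[vapply(miss_map, length, 1L) > 0]
  for (v in to_fill) {
    if (all(is.na(dat[[v]]))) stop("variable ", v, " has no observed values")
  }
  completed <- vector("list", m)
  if (!length(to_fill)) {
    for (j in seq_len(m)) completed[[j]] <- dat
  } else {
    for (j in seq_len(m)) {
      completed[[j]] <- with_seed(substream_seed(seed, paste0("impute-", method, "-", j)), {
        if (method == "chained_equations") {
          impute_chained_once(dat, variables, miss_map, to_fill, cycles)
        } else {
          impute_mvn_once(dat, variables, miss_map, to_fill)
        }
      })
    }
  }
  structure(list(completed_datasets = completed, m = as.integer(m),
                 method = method, seed = as.integer(seed),
                 variables = variables, n_missing = lengths(miss_map)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d (%s), %d variable(s) with missing values\n",
              x$m, x$method, sum(x$n_missing > 0)))
  invisible(x)
}

impute_chained_once <- function(dat, variables, miss_map, to_fill, cycles) {
  work <- dat
  # initial fill: sample from the observed marginal
  for (v in to_fill) {
    idx <- miss_map[[v]]
    obs <- work[[v]][!is.na(work[[v]])]
    work[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
  }
  for (cyc in seq_len(cycles)) {
    for (v in to_fill) {
      idx <- miss_map[[v]]
      predictors <- setdiff(variables, v)
      mf <- work
      mf[[".y"]] <- NULL
      for (pv in predictors) {
        mf[[pv]] <- factor(as.character(mf[[pv]]))
        if (nlevels(mf[[pv]]) < 2) mf[[pv]] <- NULL
      }
      predictors <- intersect(predictors, names(mf))
      if (!length(predictors)) predictors <- "1"
      vals <- draw_conditional(mf, v, predictors, idx)
      if (v == "outcome_weekly") vals <- as.integer(vals)
      work[[v]][idx] <- vals
    }
  }
  work
}

impute_mvn_once <- function(dat, variables, miss_map, to_fill) {
  # indicator coding (first level dropped per variable)
  enc <- list()
  for (v in variables) {
    lv <- if (v == "outcome_weekly") c("0", "1") else variable_levels(v)
    x <- factor(as.character(dat[[v]]), levels = lv)
    M <- matrix(NA_real_, nrow(dat), length(lv) - 1L,
                dimnames = list(NULL, paste0(v, "::", lv[-1])))
    obs <- !is.na(x)
    for (k in seq_along(lv[-1])) M[obs, k] <- as.numeric(x[obs] == lv[k + 1L])
    enc[[v]] <- M
  }
  Z <- do.call(cbind, enc)
  cc <- stats::complete.cases(Z)
  if (sum(cc) < ncol(Z) + 2) stop("too few complete cases for multivariate-normal imputation")
  boot <- sample(which(cc), sum(cc), replace = TRUE)  # parameter uncertainty
  mu <- colMeans(Z[boot, , drop = FALSE])
  Sg <- stats::cov(Z[boot, , drop = FALSE]) + diag(1e-6, ncol(Z))
  work <- dat
  for (i in which(!cc)) {
    o <- !is.na(Z[i, ]); mq <- is.na(Z[i, ])
    if (!any(o)) {
      ev <- eigen(Sg, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
      Z[i, ] <- mu + L %*% stats::rnorm(ncol(Z))
      next
    }
    cond_mu <- mu[mq] + Sg[mq, o, drop = FALSE] %*%
      solve(Sg[o, o, drop = FALSE], Z[i, o] - mu[o])
    cond_S <- Sg[mq, mq, drop = FALSE] - Sg[mq, o, drop = FALSE] %*%
      solve(Sg[o, o, drop = FALSE], Sg[o, mq, drop = FALSE])
    ev <- eigen(cond_S, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
    Z[i, mq] <- cond_mu + L %*% stats::rnorm(sum(mq))
  }
  # probabilistic rounding back to categories
  for (v in to_fill) {
    idx <- miss_map[[v]]
    lv <- if (v == "outcome_weekly") c("0", "1") else variable_levels(v)
    cols <- paste0(v, "::", lv[-1])
    for (i in idx) {
      p_rest <- pmin(pmax(Z[i, cols], 0), 1)
      p <- c(max(0, 1 - sum(p_rest)), p_rest)
      p <- p / sum(p)
      val <- lv[sample.int(length(lv), 1L, prob = p)]
      work[[v]][i] <- if (v == "outcome_weekly") as.integer(val) else val
    }
  }
  work
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines `m` per-imputation estimates and their variances: pooled mean
#' `qbar`, within-imputation variance `W` (mean of the variances),
#' between-imputation variance `B` (sample variance of the estimates), total
#' variance `T = W + (1 + 1/m) B`, Barnard-Rubin small-sample degrees of
#' freedom, and the Monte Carlo standard error of the pooled point estimate,
#' `sqrt(B / m)`.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances numeric vector of per-imputation squared SEs.
#' @param df_complete complete-data degrees of freedom for the
#'   Barnard-Rubin correction (default `Inf`, giving the classical df).
#' @return an object of class `pooled_estimate`: list with `qbar`, `W`, `B`,
#'   `T`, `df`, `mcse`, `m`.
#' @export
#' @examples
#' pool_rubin(c(0.1, 0.2, 0.3), c(0.04, 0.04, 0.04))
pool_rubin <- function(estimates, variances, df_complete = Inf) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool")
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (any(variances <= 0)) stop("variances must be positive")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tot <- W + (1 + 1 / m) * B
  stopifnot(Tot >= W)
  if (B < .Machine$double.eps * max(1, W)) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / m) * B / Tot
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_complete)) {
      df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  structure(list(qbar = qbar, W = W, B = B, T = Tot, df = df,
                 mcse = sqrt(B / m), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate over m = %d: %.4f (total var %.5f = W %.5f + (1+1/m)B, B = %.5f, df %.1f, MCSE %.5f)\n",
              x$m, x$qbar, x$T, x$W, x$B, x$df, x$mcse))
  invisible(x)
}

#' Monte Carlo error check for a pooled estimate
#'
#' Reports the Monte Carlo standard error of the pooled estimate and its
#' ratio to the total standard error; a ratio above 0.1 flags that more
#' imputations are advisable.
#'
#' @param pooled a `pooled_estimate`.
#' @param threshold flag threshold for `mcse / sqrt(T)`.
#' @return list with `mcse`, `ratio`, `flag`, `m`.
#' @export
monte_carlo_error_check <- function(pooled, threshold = 0.1) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  ratio <- if (pooled$T > 0) pooled$mcse / sqrt(pooled$T) else 0
  list(mcse = pooled$mcse, ratio = ratio, flag = ratio > threshold,
       m = pooled$m)
}
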