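# Synthetic-data generator: school tables with stratified block
# randomization, calibrated random-intercept outcome model, trial and
# serial-survey participant tables with known ground truth.

#' Generate a school table
#'
#' Draws the six school-level stratification variables from the configured
#' strata distribution.  For the trial population, arms are assigned by
#' stratified block randomization: schools are paired within each stratum
#' and one of each pair randomized to each arm; left-over schools are
#' allocated so the overall arm school counts match the configuration
#' exactly.  Survey schools are England-only and receive no arm.
#'
#' @param config a `transport_config`.
#' @param population `"trial"` or a survey year (e.g. `"2021"` or `2021`).
#' @param seed integer seed.
#' @return data.frame with columns `school_id`, the six `strat_*` columns
#'   and, for the trial, `arm`.
#' @export
generate_schools <- function(config, population = "trial", seed = config$seed) {
  validate_config(config)
  population <- as.character(population)
  is_trial <- identical(population, "trial")
  if (!is_trial && !population %in% names(config$surveys)) {
    stop("unknown survey year: ", population)
  }
  n <- if (is_trial) config$trial$n_schools else config$surveys[[population]]$n_schools
  if (is_trial && sum(config$trial$arm_schools) > n) {
    stop("arm school counts exceed the number of schools")
  }
  with_seed(substream_seed(seed, paste0("schools-", population)), {
    prefix <- if (is_trial) "trial" else paste0("survey", population)
    tab <- data.frame(
      school_id = sprintf("%s:s%03d", prefix, seq_len(n)),
      stringsAsFactors = FALSE
    )
    for (s in .strata_names) {
      p <- config$strata[[s]]
      draw <- sample(names(p), n, replace = TRUE, prob = p)
      if (!is_trial && s == "country") draw <- rep("england", n)
      tab[[paste0("strat_", s)]] <- draw
    }
    if (is_trial) {
      tab$arm <- assign_arms_stratified(
        interaction(tab[paste0("strat_", .strata_names)], drop = TRUE),
        config$trial$arm_schools
      )
    }
    tab
  })
}

# Stratified block randomization with exact overall arm totals.  Within each
# stratum schools are paired and each pair split across arms; the odd
# left-over schools are then randomized subject to the exact overall counts.
assign_arms_stratified <- function(strata, arm_counts) {
  n <- length(strata)
  stopifnot(sum(arm_counts) == n)
  arm <- character(n)
  odd <- integer(0)
  for (s in levels(factor(strata))) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    npair <- length(idx) %/% 2L
    if (npair > 0) {
      for (j in seq_len(npair)) {
        pair <- idx[c(2L * j - 1L, 2L * j)]
        arm[pair] <- sample(c("control", "intervention"))
      }
    }
    if (length(idx) %% 2L == 1L) odd <- c(odd, idx[length(idx)])
  }
  need_int <- arm_counts[["intervention"]] - sum(arm == "intervention")
  if (need_int < 0 || need_int > length(odd)) {
    # Degenerate stratum layout: fall back to simple randomization of the
    # odd schools plus pair flips to restore exact totals.
    arm[odd] <- sample(rep(c("control", "intervention"), length.out = length(odd)))
    excess <- sum(arm == "intervention") - arm_counts[["intervention"]]
    from <- if (excess > 0) "intervention" else "control"
    to <- setdiff(c("control", "intervention"), from)
    cand <- which(arm == from)
    flip <- cand[sample.int(length(cand), abs(excess))]
    arm[flip] <- to
  } else {
    pick <- odd[sample.int(length(odd), need_int)]
    arm[pick] <- "intervention"
    arm[setdiff(odd, pick)] <- "control"
  }
  arm
}

# Joint distribution of (smoking_status, age_first_cig) under the
# consistency hook: never-smokers always report age-first "never"; among the
# rest the age-first distribution is renormalized so the configured marginal
# is preserved whenever it is feasible (P(af = never) >= P(status = never)).
smoking_agefirst_joint <- function(marginals, hook = TRUE) {
  ps <- marginals$smoking_status
  pa <- marginals$age_first_cig
  if (!hook) {
    joint <- outer(ps, pa)
    dimnames(joint) <- list(names(ps), names(pa))
    return(joint)
  }
  p_never_s <- ps[["never"]]
  smoker_lv <- setdiff(names(ps), "never")
  q_never <- max(0, (pa[["never"]] - p_never_s) / (1 - p_never_s))
  rest <- pa[setdiff(names(pa), "never")]
  rest <- rest / sum(rest) * (1 - q_never)
  cond_af <- c(never = q_never, rest)[names(pa)]
  joint <- matrix(0, length(ps), length(pa),
                  dimnames = list(names(ps), names(pa)))
  joint["never", "never"] <- p_never_s
  for (s in smoker_lv) joint[s, ] <- ps[[s]] * cond_af
  joint
}

# Enumerate the full joint distribution of the covariate linear predictor
# eta = sum_j beta_j[x_j] with cell probabilities, for exact expectations.
# Returns a data.frame of cells (one column per covariate) with prob and eta.
covariate_cells <- function(marginals, coefs, hook = TRUE,
                            extra_coefs = NULL) {
  joint_sa <- smoking_agefirst_joint(marginals, hook)
  sa <- which(joint_sa > 0, arr.ind = TRUE)
  sa_cells <- data.frame(
    smoking_status = rownames(joint_sa)[sa[, 1]],
    age_first_cig = colnames(joint_sa)[sa[, 2]],
    p_sa = joint_sa[sa],
    stringsAsFactors = FALSE
  )
  others <- setdiff(covariate_names(), c("smoking_status", "age_first_cig"))
  grids <- c(list(sa = seq_len(nrow(sa_cells))),
             lapply(marginals[others], names))
  cells <- expand.grid(grids, stringsAsFactors = FALSE)
  out <- cbind(sa_cells[cells$sa, c("smoking_status", "age_first_cig")],
               cells[others])
  prob <- sa_cells$p_sa[cells$sa]
  eta <- numeric(nrow(out))
  total_coefs <- coefs
  for (v in covariate_names()) {
    if (v %in% others) prob <- prob * marginals[[v]][out[[v]]]
    b <- total_coefs[[v]]
    if (!is.null(b)) eta <- eta + b[out[[v]]]
    if (!is.null(extra_coefs[[v]])) eta <- eta + extra_coefs[[v]][out[[v]]]
  }
  out$prob <- unname(prob)
  out$eta <- unname(eta)
  rownames(out) <- NULL
  out
}

#' Solve the outcome-model intercept for a target marginal prevalence
#'
#' Finds the intercept `alpha` such that the marginal outcome prevalence of
#' the random-intercept logistic model, averaged exactly over the configured
#' covariate distribution, the arm assignment (if supplied) and the school
#' random intercept (Gauss-Hermite quadrature), equals `target` to within
#' 1e-10.
#'
#' @param target desired marginal prevalence, in (0, 1).
#' @param marginals list of covariate marginal probability vectors.
#' @param coefs list of covariate log-odds vectors (as in the config
#'   `outcome_model$coefs`).
#' @param sigma_u school random-intercept SD (logit scale).
#' @param treatment optional list with elements `log_or`, `prob` (proportion
#'   assigned to intervention) and optionally `interactions`, so the
#'   calibration averages over both arms.
#' @param hook apply the smoking-status / age-first consistency constraint
#'   when enumerating the covariate distribution.
#' @return the intercept (numeric scalar).
#' @export
#' @examples
#' # with no covariate effects and no clustering this is just the logit
#' solve_intercept(0.5, marginals = make_default_config()$trial$marginals,
#'                 coefs = NULL, sigma_u = 0)
solve_intercept <- function(target, marginals, coefs, sigma_u,
                            treatment = NULL, hook = TRUE) {
  stopifnot(target > 0, target < 1, sigma_u >= 0)
  if (is.null(coefs)) {
    coefs <- lapply(marginals, function(p) stats::setNames(rep(0, length(p)), names(p)))
  }
  cells <- covariate_cells(marginals, coefs, hook)
  eta <- cells$eta
  prob <- cells$prob
  if (!is.null(treatment)) {
    pi1 <- treatment$prob
    eta1 <- eta + treatment$log_or
    if (length(treatment$interactions)) {
      extra <- covariate_cells(marginals, coefs, hook,
                               extra_coefs = treatment$interactions)
      eta1 <- extra$eta + treatment$log_or
    }
    eta <- c(eta, eta1)
    prob <- c(prob * (1 - pi1), cells$prob * pi1)
  }
  gh <- gauss_hermite_normal(25L)
  prev <- function(alpha) {
    sum(prob * marginal_expit(alpha + eta, sigma_u, gh)) - target
  }
  lo <- logit(target) - 4 - 2 * max(abs(cells$eta)) - sigma_u
  hi <- logit(target) + 4 + 2 * max(abs(cells$eta)) + sigma_u
  if (prev(lo) > 0 || prev(hi) < 0) stop("no intercept in search bracket")
  stats::uniroot(prev, c(lo, hi), tol = 1e-12)$root
}

# Draw covariates for n individuals from the configured marginals, honouring
# the consistency hook and optional school-level covariate clustering
# (per-school normal perturbation of category log-probabilities).
sample_covariates <- function(n, marginals, school, hook = TRUE,
                              covariate_sd = 0) {
  out <- data.frame(row.names = seq_len(n))
  schools <- unique(school)
  perturb <- function(p, shift) {
    q <- exp(log(p) + shift)
    q / sum(q)
  }
  draw_cat <- function(p) {
    if (covariate_sd > 0) {
      x <- character(n)
      for (s in schools) {
        idx <- which(school == s)
        ps <- perturb(p, stats::rnorm(length(p), 0, covariate_sd))
        x[idx] <- sample(names(p), length(idx), replace = TRUE, prob = ps)
      }
      x
    } else {
      sample(names(p), n, replace = TRUE, prob = p)
    }
  }
  for (v in setdiff(covariate_names(), "age_first_cig")) {
    out[[v]] <- draw_cat(marginals[[v]])
  }
  # age-first conditional on smoking status under the hook
  joint <- smoking_agefirst_joint(marginals, hook)
  af <- character(n)
  for (s in rownames(joint)) {
    idx <- which(out$smoking_status == s)
    if (!length(idx)) next
    cond <- joint[s, ]
    if (sum(cond) == 0) cond <- marginals$age_first_cig
    af[idx] <- sample(colnames(joint), length(idx), replace = TRUE,
                      prob = cond / sum(cond))
  }
  out$age_first_cig <- af
  out$age <- as.integer(out$age)
  out
}

# Allocate n students across k schools: multinomial sizes with equal
# school probabilities, adjusted so every school has at least min_size
# students and the total is exact.
allocate_students <- function(n, k, min_size = 2L) {
  sizes <- as.vector(stats::rmultinom(1, n, rep(1 / k, k)))
  while (any(sizes < min_size)) {
    i <- which.min(sizes)
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  sizes
}

#' Generate a synthetic trial dataset
#'
#' Simulates the full cluster trial: schools with stratified block
#' randomization, students allocated to schools so per-arm totals are exact,
#' baseline covariates from the trial marginals, and the weekly-smoking
#' outcome at follow-up from the calibrated school random-intercept logistic
#' model with the configured intervention effect.
#'
#' @param config a `transport_config`.
#' @param seed integer seed (default taken from the config).
#' @return a harmonized participant data.frame (see [data_dictionary()]).
#' @export
#' @examples
#' cfg <- scale_config(make_default_config(), 20)
#' trial <- generate_trial(cfg, seed = 1)
#' table(trial$arm)
generate_trial <- function(config, seed = config$seed) {
  validate_config(config)
  schools <- generate_schools(config, "trial", seed)
  om <- config$outcome_model
  pi1 <- config$trial$arm_students[["intervention"]] / sum(config$trial$arm_students)
  alpha <- solve_intercept(
    om$target_prevalence, config$trial$marginals, om$coefs, om$sigma_u,
    treatment = list(log_or = om$treatment_log_or, prob = pi1,
                     interactions = om$interactions),
    hook = config$consistency_hook
  )
  with_seed(substream_seed(seed, "trial-students"), {
    rows <- list()
    for (a in c("control", "intervention")) {
      sch <- schools[schools$arm == a, , drop = FALSE]
      sizes <- allocate_students(config$trial$arm_students[[a]], nrow(sch))
      rows[[a]] <- data.frame(
        school_row = rep(seq_len(nrow(sch)), sizes),
        school_id = rep(sch$school_id, sizes),
        arm = a, stringsAsFactors = FALSE
      )
      for (s in paste0("strat_", .strata_names)) {
        rows[[a]][[s]] <- rep(sch[[s]], sizes)
      }
    }
    dat <- rbind(rows$control, rows$intervention)
    dat$school_row <- NULL
    cov <- sample_covariates(nrow(dat), config$trial$marginals, dat$school_id,
                             config$consistency_hook, config$covariate_sd)
    dat <- cbind(dat, cov)
    u <- stats::rnorm(config$trial$n_schools, 0, om$sigma_u)
    names(u) <- schools$school_id
    eta <- alpha + u[dat$school_id] +
      (dat$arm == "intervention") * om$treatment_log_or
    for (v in covariate_names()) {
      eta <- eta + om$coefs[[v]][as.character(dat[[v]])]
      if (!is.null(om$interactions[[v]])) {
        eta <- eta + (dat$arm == "intervention") *
          om$interactions[[v]][as.character(dat[[v]])]
      }
    }
    dat$outcome_weekly <- stats::rbinom(nrow(dat), 1, expit(unname(eta)))
    dat$source <- "trial"
    dat$year <- config$trial$year
    dat[, .participant_columns]
  })
}

#' Generate a synthetic survey dataset
#'
#' Simulates one cross-sectional school survey wave: covariates only (no arm,
#' no follow-up outcome), with year-specific marginals and school clustering.
#' Weekly smokers appear as a level of `smoking_status`, so the survey
#' prevalence of weekly smoking is checkable against the configured marginal.
#'
#' @param config a `transport_config`.
#' @param year a survey year present in the configuration.
#' @param seed integer seed.
#' @param n_students optional override of the configured sample size.
#' @return a harmonized participant data.frame.
#' @export
#' @examples
#' cfg <- scale_config(make_default_config(), 20)
#' sv <- generate_survey(cfg, 2004, seed = 1)
#' nrow(sv)
generate_survey <- function(config, year, seed = config$seed,
                            n_students = NULL) {
  validate_config(config)
  year <- as.character(year)
  if (!year %in% names(config$surveys)) stop("unknown survey year: ", year)
  spec <- config$surveys[[year]]
  n <- as.integer(n_students %||% spec$n_students)
  schools <- generate_schools(config, year, seed)
  with_seed(substream_seed(seed, paste0("survey-students-", year)), {
    sizes <- allocate_students(n, nrow(schools))
    dat <- data.frame(
      school_id = rep(schools$school_id, sizes),
      stringsAsFactors = FALSE
    )
    for (s in paste0("strat_", .strata_names)) {
      dat[[s]] <- rep(schools[[s]], sizes)
    }
    cov <- sample_covariates(n, spec$marginals, dat$school_id,
                             config$consistency_hook, config$covariate_sd)
    dat <- cbind(dat, cov)
    dat$arm <- NA_character_
    dat$outcome_weekly <- NA_integer_
    dat$source <- "target"
    dat$year <- as.integer(year)
    dat[, .participant_columns]
  })
}

#' Ground-truth transported estimand for a configuration
#'
#' The arm coefficient the transported analysis targets in a given survey
#' year.  With a homogeneous intervention effect (no interaction terms) the
#' conditional log-odds ratio is the configured `treatment_log_or` in every
#' target population, returned analytically.  With effect modification the
#' probability limit is obtained by brute force: a large two-arm cohort is
#' simulated with covariates drawn from the year's marginals, outcomes from
#' the configured outcome model, and the (unweighted) analysis model is fit
#' to report its arm coefficient.
#'
#' @param config a `transport_config`.
#' @param year survey year.
#' @param n_sim cohort size for the brute-force path.
#' @param seed seed for the brute-force path.
#' @return list with `estimand` (log-odds ratio), `method`
#'   (`"analytic"` or `"brute_force"`) and `year`.
#' @export
true_transported_estimand <- function(config, year, n_sim = 50000L,
                                      seed = config$seed) {
  validate_config(config)
  year <- as.character(year)
  if (!year %in% names(config$surveys)) stop("unknown survey year: ", year)
  om <- config$outcome_model
  if (!length(om$interactions)) {
    return(list(estimand = om$treatment_log_or, method = "analytic",
                year = as.integer(year)))
  }
  marg <- config$surveys[[year]]$marginals
  alpha <- solve_intercept(om$target_prevalence, config$trial$marginals,
                           om$coefs, om$sigma_u,
                           treatment = list(log_or = om$treatment_log_or,
                                            prob = 0.5,
                                            interactions = om$interactions),
                           hook = config$consistency_hook)
  with_seed(substream_seed(seed, paste0("estimand-", year)), {
    n_sch <- 100L
    school <- sprintf("sim:s%03d", sample.int(n_sch, n_sim, replace = TRUE))
    cov <- sample_covariates(n_sim, marg, school, config$consistency_hook, 0)
    arm <- sample(rep(c("control", "intervention"), length.out = n_sim))
    u <- stats::rnorm(n_sch, 0, om$sigma_u)
    names(u) <- sprintf("sim:s%03d", seq_len(n_sch))
    eta <- alpha + u[school] + (arm == "intervention") * om$treatment_log_or
    for (v in covariate_names()) {
      eta <- eta + om$coefs[[v]][as.character(cov[[v]])]
      if (!is.null(om$interactions[[v]])) {
        eta <- eta + (arm == "intervention") *
          om$interactions[[v]][as.character(cov[[v]])]
      }
    }
    y <- stats::rbinom(n_sim, 1, expit(unname(eta)))
    fit <- lme4::glmer(y ~ arm + (1 | school), family = stats::binomial(),
                       nAGQ = 0L,
                       data = data.frame(y = y, arm = factor(arm,
                         levels = c("control", "intervention")),
                         school = school))
    list(estimand = unname(lme4::fixef(fit)[["armintervention"]]),
         method = "brute_force", year = as.integer(year))
  })
}
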