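# Generator configuration: per-population covariate marginals, the
# random-intercept outcome model, school strata and sample sizes.

# Published category counts per population column.  Proportions are taken as
# count / sum(count) within each variable, which guarantees exact sum-to-one
# (printed percentages are rounded and do not always sum to 100).
.count_tables <- list(
  trial = list(
    gender            = c(boy = 4420, girl = 4336),
    age               = c(`12` = 6830, `13` = 1926),
    ethnicity         = c(white = 8073, minority = 683),
    smoking_status    = c(never = 5105, occ_exp_ex = 3294, weekly = 357),
    age_first_cig     = c(never = 5069, le10 = 1383, y11 = 1217, y12 = 1016,
                          y13 = 71),
    lives_with_smoker = c(yes = 4527, no = 4229),
    lesson_smoking    = c(yes = 5017, no = 2321, dont_know = 1418)
  ),
  `2004` = list(
    gender            = c(boy = 2073, girl = 1885),
    age               = c(`12` = 1976, `13` = 1982),
    ethnicity         = c(white = 3388, minority = 570),
    smoking_status    = c(never = 2818, occ_exp_ex = 998, weekly = 142),
    age_first_cig     = c(never = 2699, le10 = 420, y11 = 332, y12 = 400,
                          y13 = 107),
    lives_with_smoker = c(yes = 1821, no = 2137),
    lesson_smoking    = c(yes = 2323, no = 1255, dont_know = 380)
  ),
  `2006` = list(
    gender            = c(boy = 1661, girl = 1716),
    age               = c(`12` = 1709, `13` = 1668),
    ethnicity         = c(white = 2935, minority = 442),
    smoking_status    = c(never = 2463, occ_exp_ex = 788, weekly = 100),
    age_first_cig     = c(never = 2364, le10 = 290, y11 = 297, y12 = 426,
                          y13 = 0),
    lives_with_smoker = c(yes = 1628, no = 1749),
    lesson_smoking    = c(yes = 1942, no = 1064, dont_know = 371)
  ),
  `2014` = list(
    gender            = c(boy = 1605, girl = 1540),
    age               = c(`12` = 1591, `13` = 1554),
    ethnicity         = c(white = 2692, minority = 453),
    smoking_status    = c(never = 2538, occ_exp_ex = 519, weekly = 88),
    age_first_cig     = c(never = 2431, le10 = 208, y11 = 186, y12 = 320,
                          y13 = 0),
    lives_with_smoker = c(yes = 1283, no = 1862),
    lesson_smoking    = c(yes = 1896, no = 899, dont_know = 350)
  ),
  `2016` = list(
    gender            = c(boy = 2393, girl = 2481),
    age               = c(`12` = 2129, `13` = 2745),
    ethnicity         = c(white = 4255, minority = 619),
    smoking_status    = c(never = 4352, occ_exp_ex = 468, weekly = 54),
    age_first_cig     = c(never = 4260, le10 = 117, y11 = 132, y12 = 194,
                          y13 = 171),
    lives_with_smoker = c(yes = 1433, no = 3441),
    lesson_smoking    = c(yes = 2997, no = 1087, dont_know = 790)
  ),
  `2021` = list(
    gender            = c(boy = 1844, girl = 1743),
    age               = c(`12` = 1605, `13` = 1982),
    ethnicity         = c(white = 2590, minority = 997),
    smoking_status    = c(never = 3386, occ_exp_ex = 194, weekly = 7),
    age_first_cig     = c(never = 3332, le10 = 65, y11 = 61, y12 = 68,
                          y13 = 61),
    lives_with_smoker = c(yes = 1008, no = 2579),
    lesson_smoking    = c(yes = 2253, no = 692, dont_know = 642)
  )
)

.survey_n <- c(`2004` = 3958, `2006` = 3377, `2014` = 3145,
               `2016` = 4874, `2021` = 3587)

.counts_to_marginals <- function(tab) lapply(tab, function(x) x / sum(x))

#' Default generator configuration
#'
#' Builds the default configuration of the synthetic-data generator: a
#' two-arm school-clustered trial (59 schools; 30 intervention schools with
#' 4563 students, 29 control schools with 4193) and five serial
#' cross-sectional school surveys (2004, 2006, 2014, 2016, 2021) whose
#' covariate marginals drift over time -- weekly smoking falls from 3.6% to
#' 0.2%, the ethnic-minority share rises from 14.4% to 27.8%, and residence
#' with a smoker falls from 46.0% to 28.1%.  The trial outcome model is a
#' school random-intercept logistic model for weekly smoking at the two-year
#' follow-up; its intercept is solved numerically at generation time so the
#' model-implied marginal prevalence equals the configured target (4.1% by
#' default, at the configured arm split and intervention effect).
#'
#' @param treatment_log_or intervention effect on the conditional log-odds
#'   scale; default `log(0.85)`.
#' @param sigma_u standard deviation of the school random intercept on the
#'   logit scale.
#' @param interactions optional named list of effect-modification terms:
#'   per covariate, a named numeric vector of extra intervention log-odds per
#'   level (added to `treatment_log_or`).
#' @param covariate_sd school-level covariate clustering: standard deviation
#'   of a per-school normal perturbation of the category log-probabilities
#'   (0 disables clustering and keeps configured marginals exact).
#' @param consistency_hook if `TRUE` (default), never-smokers are always
#'   generated with age-at-first-cigarette "never", avoiding logically
#'   impossible records; the age-first marginal is renormalized accordingly.
#' @param seed default master seed carried in the configuration.
#' @return an object of class `transport_config`.
#' @export
#' @examples
#' cfg <- make_default_config()
#' cfg$trial$marginals$ethnicity
make_default_config <- function(treatment_log_or = log(0.85),
                                sigma_u = 0.3,
                                interactions = list(),
                                covariate_sd = 0,
                                consistency_hook = TRUE,
                                seed = 1L) {
  surveys <- lapply(names(.survey_n), function(y) {
    n <- .survey_n[[y]]
    list(
      year = as.integer(y),
      n_students = as.integer(n),
      # School sample sizes are not published per wave; roughly 35 students
      # per sampled school is assumed (documented in the methods vignette).
      n_schools = max(20L, as.integer(round(n / 35))),
      marginals = .counts_to_marginals(.count_tables[[y]])
    )
  })
  names(surveys) <- names(.survey_n)

  cfg <- structure(list(
    trial = list(
      n_schools = 59L,
      arm_schools = c(control = 29L, intervention = 30L),
      arm_students = c(control = 4193L, intervention = 4563L),
      year = 2004L,
      marginals = .counts_to_marginals(.count_tables$trial)
    ),
    surveys = surveys,
    outcome_model = list(
      treatment_log_or = treatment_log_or,
      # Conditional log-odds for weekly smoking at follow-up given baseline
      # covariates; baseline smoking behaviour dominates, consistent with
      # strong tracking of adolescent smoking.
      coefs = list(
        gender            = c(boy = 0, girl = 0.2),
        age               = c(`12` = 0, `13` = 0.3),
        ethnicity         = c(white = 0, minority = -0.3),
        smoking_status    = c(never = 0, occ_exp_ex = 1.6, weekly = 3.0),
        age_first_cig     = c(never = 0, le10 = 0.6, y11 = 0.5, y12 = 0.4,
                              y13 = 0.3),
        lives_with_smoker = c(yes = 0.5, no = 0),
        lesson_smoking    = c(yes = 0, no = 0.1, dont_know = 0)
      ),
      interactions = interactions,
      sigma_u = sigma_u,
      target_prevalence = 0.041
    ),
    strata = list(
      country     = c(england = 0.6, wales = 0.4),
      school_type = c(state = 0.9, independent = 0.1),
      sex_mix     = c(mixed = 0.8, single = 0.2),
      language    = c(english = 0.85, welsh = 0.15),
      size_large  = c(no = 0.5, yes = 0.5),
      fsm_high    = c(no = 0.5, yes = 0.5)
    ),
    covariate_sd = covariate_sd,
    consistency_hook = isTRUE(consistency_hook),
    seed = as.integer(seed)
  ), class = "transport_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks that every marginal probability vector sums to one (within 1e-12),
#' sample sizes are positive integers, the random-intercept SD is
#' non-negative, arm school counts sum to the school total, and every survey
#' year carries marginals for every harmonized covariate.
#'
#' @param config a `transport_config`.
#' @return the config, invisibly; errors if invalid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "transport_config"))
  check_marg <- function(m, where) {
    miss <- setdiff(covariate_names(), names(m))
    if (length(miss)) {
      stop(where, ": missing marginals for ", paste(miss, collapse = ", "))
    }
    for (v in covariate_names()) {
      p <- m[[v]]
      if (!setequal(names(p), variable_levels(v))) {
        stop(where, ": levels of ", v, " do not match schema")
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
        stop(where, ": marginal for ", v, " is not a probability vector")
      }
    }
  }
  check_marg(config$trial$marginals, "trial")
  tr <- config$trial
  if (tr$n_schools <= 0 || any(tr$arm_schools <= 0) || any(tr$arm_students <= 0)) {
    stop("trial sample sizes must be positive")
  }
  if (sum(tr$arm_schools) != tr$n_schools) {
    stop("arm school counts must sum to n_schools")
  }
  for (y in names(config$surveys)) {
    sv <- config$surveys[[y]]
    if (sv$n_students <= 0 || sv$n_schools <= 0) {
      stop("survey ", y, ": sample sizes must be positive")
    }
    check_marg(sv$marginals, paste0("survey ", y))
  }
  if (config$outcome_model$sigma_u < 0) stop("sigma_u must be >= 0")
  tp <- config$outcome_model$target_prevalence
  if (tp <= 0 || tp >= 1) stop("target prevalence must be in (0, 1)")
  for (s in .strata_names) {
    p <- config$strata[[s]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-12) {
      stop("strata distribution for ", s, " is not a probability vector")
    }
  }
  invisible(config)
}

#' Scale a configuration's sample sizes
#'
#' Divides student and school counts by `factor` (rounding, keeping at least
#' two schools per trial arm), e.g. for a small test-sized bundle.
#'
#' @param config a `transport_config`.
#' @param factor divisor applied to all sample sizes.
#' @return the scaled `transport_config`.
#' @export
scale_config <- function(config, factor) {
  stopifnot(factor > 0)
  sc <- function(n, lo = 1L) {
    stats::setNames(pmax(lo, as.integer(round(n / factor))), names(n))
  }
  config$trial$arm_students <- sc(config$trial$arm_students)
  config$trial$arm_schools <- sc(config$trial$arm_schools, lo = 2L)
  config$trial$n_schools <- sum(config$trial$arm_schools)
  for (y in names(config$surveys)) {
    config$surveys[[y]]$n_students <- sc(config$surveys[[y]]$n_students)
    config$surveys[[y]]$n_schools <- sc(config$surveys[[y]]$n_schools, lo = 5L)
  }
  validate_config(config)
  config
}

#' @export
print.transport_config <- function(x, ...) {
  tr <- x$trial
  cat("Generator configuration\n")
  cat(sprintf("  trial : %d schools (%d intervention / %d control), %d students\n",
              tr$n_schools, tr$arm_schools[["intervention"]],
              tr$arm_schools[["control"]], sum(tr$arm_students)))
  for (y in names(x$surveys)) {
    sv <- x$surveys[[y]]
    cat(sprintf("  survey %s: %d students in %d schools\n",
                y, sv$n_students, sv$n_schools))
  }
  om <- x$outcome_model
  cat(sprintf("  outcome: treatment log-OR %.4f (OR %.3f), sigma_u %.2f, target prevalence %.3f\n",
              om$treatment_log_or, exp(om$treatment_log_or), om$sigma_u,
              om$target_prevalence))
  if (length(om$interactions)) {
    cat("  effect modification on:", paste(names(om$interactions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a `transport_config`.
#' @param path file path.
#' @return `read_config` returns a validated `transport_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  # yaml drops names of atomic vectors; serialize them as maps
  as_maps <- function(x) {
    if (is.list(x)) lapply(x, as_maps)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_maps(unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  relist_named <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE)) &&
        all(vapply(x, length, 1L) == 1L) && !is.null(names(x))) {
      unlist(x)
    } else if (is.list(x)) {
      lapply(x, relist_named)
    } else x
  }
  cfg <- structure(relist_named(raw), class = "transport_config")
  cfg$trial$arm_schools <- as.integer(round(cfg$trial$arm_schools))
  cfg$trial$arm_students <- as.integer(round(cfg$trial$arm_students))
  cfg$trial$n_schools <- as.integer(cfg$trial$n_schools)
  validate_config(cfg)
  cfg
}
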