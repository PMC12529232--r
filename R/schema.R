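# Harmonized participant schema shared by the trial and the survey waves.
# Every categorical variable is stored as character with a fixed level set;
# missing values are NA.  The first level of each set is the modelling
# reference level throughout the package.

.covariate_levels <- list(
  gender            = c("boy", "girl"),
  age               = c("12", "13"),
  ethnicity         = c("white", "minority"),
  smoking_status    = c("never", "occ_exp_ex", "weekly"),
  age_first_cig     = c("never", "le10", "y11", "y12", "y13"),
  lives_with_smoker = c("yes", "no"),
  lesson_smoking    = c("yes", "no", "dont_know")
)

.strata_names <- c("country", "school_type", "sex_mix", "language",
                   "size_large", "fsm_high")

.strata_levels <- list(
  country     = c("england", "wales"),
  school_type = c("state", "independent"),
  sex_mix     = c("mixed", "single"),
  language    = c("english", "welsh"),
  size_large  = c("no", "yes"),
  fsm_high    = c("no", "yes")
)

.participant_columns <- c(
  "source", "year", "school_id", "arm",
  names(.covariate_levels),
  paste0("strat_", .strata_names),
  "outcome_weekly"
)

#' Names of the harmonized individual-level covariates
#'
#' The covariates used by default in the selection model: gender identity,
#' age (12 or 13 years), ethnicity (white / minority), smoking status
#' (never; occasional, experimental or ex-smoker; weekly), age at first
#' cigarette, residence with a smoker, and whether the student had a school
#' lesson on smoking in the past 12 months.
#'
#' @return character vector of column names.
#' @export
covariate_names <- function() names(.covariate_levels)

#' Levels of a harmonized categorical variable
#'
#' @param variable a covariate name (see [covariate_names()]) or one of the
#'   school stratification variables.
#' @return character vector of levels, reference level first.
#' @export
variable_levels <- function(variable) {
  lv <- c(.covariate_levels, .strata_levels)[[variable]]
  if (is.null(lv)) stop("unknown variable: ", variable)
  lv
}

#' Names of the school-level stratification variables
#'
#' The six school-level variables used to stratify randomization: country
#' (England or Wales), school type (state or independent), mixed or
#' single-sex intake, language of instruction, year-group size above the
#' sampling-frame median, and free-school-meal entitlement above the national
#' median.  On participant tables they are prefixed `strat_`.
#'
#' @param prefixed if `TRUE`, return the participant-table column names.
#' @return character vector.
#' @export
stratification_names <- function(prefixed = FALSE) {
  if (prefixed) paste0("strat_", .strata_names) else .strata_names
}

#' Data dictionary for the harmonized participant schema
#'
#' @return a data.frame with one row per column of a harmonized participant
#'   table: column name, type, allowed levels and a short description.
#' @export
#' @examples
#' data_dictionary()
data_dictionary <- function() {
  lev <- function(v) paste(v, collapse = "|")
  rows <- list(
    c("source", "character", "trial|target", "origin of the record"),
    c("year", "integer", "", "survey year; 2004 for trial records"),
    c("school_id", "character", "", "school identifier, namespaced by source"),
    c("arm", "character", "control|intervention",
      "randomized arm; NA for target records"),
    c("gender", "character", lev(.covariate_levels$gender), "gender identity"),
    c("age", "integer", "12|13", "age in years after harmonization recode"),
    c("ethnicity", "character", lev(.covariate_levels$ethnicity),
      "ethnicity collapsed to white vs minority"),
    c("smoking_status", "character", lev(.covariate_levels$smoking_status),
      "self-reported smoking status"),
    c("age_first_cig", "character", lev(.covariate_levels$age_first_cig),
      "age when first cigarette was smoked"),
    c("lives_with_smoker", "character", lev(.covariate_levels$lives_with_smoker),
      "lives with a smoker; NA if missing or routed away"),
    c("lesson_smoking", "character", lev(.covariate_levels$lesson_smoking),
      "school lesson on smoking in past 12 months"),
    c("strat_country", "character", lev(.strata_levels$country),
      "school stratification: country"),
    c("strat_school_type", "character", lev(.strata_levels$school_type),
      "school stratification: state or independent"),
    c("strat_sex_mix", "character", lev(.strata_levels$sex_mix),
      "school stratification: mixed or single sex"),
    c("strat_language", "character", lev(.strata_levels$language),
      "school stratification: language of instruction"),
    c("strat_size_large", "character", lev(.strata_levels$size_large),
      "school stratification: year group size above median"),
    c("strat_fsm_high", "character", lev(.strata_levels$fsm_high),
      "school stratification: free school meal entitlement above median"),
    c("outcome_weekly", "integer", "0|1",
      "weekly smoking (>= 1 cigarette/week) at 2-year follow-up; trial only")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("column", "type", "levels", "description")
  out
}

# Coerce a participant data.frame's covariates to factors with the schema
# level order (reference first); used by all model-fitting code.
as_model_factors <- function(records, variables = covariate_names()) {
  for (v in variables) {
    lv <- if (v %in% names(.covariate_levels)) {
      .covariate_levels[[v]]
    } else {
      .strata_levels[[sub("^strat_", "", v)]]
    }
    if (is.null(lv)) next
    records[[v]] <- factor(as.character(records[[v]]), levels = lv)
  }
  records
}
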