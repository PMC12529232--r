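# Variable harmonization and dataset stacking: trial and survey records are
# brought to one shared schema and appended with a selection indicator.

#' Recode survey ages to the trial age range
#'
#' Eleven-year-olds are recoded to 12 and fourteen-year-olds to 13 so survey
#' ages match the trial cohort (ages 12-13).
#'
#' @param raw_age integer vector of ages in years, each in 11..14.
#' @return integer vector of ages in `{12, 13}`.
#' @export
#' @examples
#' recode_age(c(11, 12, 13, 14))
recode_age <- function(raw_age) {
  if (any(is.na(raw_age)) || any(raw_age < 11 | raw_age > 14)) {
    stop("ages must be in 11..14")
  }
  as.integer(pmin(pmax(raw_age, 12L), 13L))
}

.ethnicity_raw_levels <- c("white", "mixed race", "asian or asian british",
                           "black or black british", "chinese", "other")

#' Collapse detailed ethnicity to white / minority
#'
#' The trial's six ethnicity categories (white, mixed race, Asian or Asian
#' British, black or black British, Chinese, other) are collapsed to the
#' survey's two-level coding: white vs minority.
#'
#' @param raw character vector of trial ethnicity levels.
#' @return character vector with levels `"white"` / `"minority"`.
#' @export
#' @examples
#' collapse_ethnicity(c("white", "chinese", "mixed race"))
collapse_ethnicity <- function(raw) {
  raw_l <- tolower(trimws(as.character(raw)))
  bad <- !is.na(raw_l) & !raw_l %in% .ethnicity_raw_levels
  if (any(bad)) {
    stop("unknown ethnicity level(s): ", paste(unique(raw[bad]), collapse = ", "))
  }
  ifelse(is.na(raw_l), NA_character_,
         ifelse(raw_l == "white", "white", "minority"))
}

#' Derive the weekly-smoking outcome from cigarettes per week
#'
#' Weekly smoking is smoking at least one cigarette a week.
#'
#' @param cigs_per_week non-negative counts.
#' @return integer 0/1 vector (NA preserved).
#' @export
#' @examples
#' derive_weekly_outcome(c(0, 1, 20))
derive_weekly_outcome <- function(cigs_per_week) {
  if (any(cigs_per_week < 0, na.rm = TRUE)) stop("counts must be non-negative")
  as.integer(cigs_per_week >= 1)
}

#' Code routed-missing residence-with-smoker responses
#'
#' In the 2016 and 2021 survey waves about half the students were routed to a
#' question block without the residence-with-smoker item; their responses are
#' coded missing.  Other years are returned unchanged.
#'
#' @param records harmonized participant data.frame.
#' @param year survey year of the records.
#' @param routed logical vector (length `nrow(records)`) flagging records
#'   routed away from the item.
#' @return the records with `lives_with_smoker` set to `NA` where routed.
#' @export
code_routed_missing <- function(records, year, routed) {
  stopifnot(length(routed) == nrow(records))
  if (as.integer(year) %in% c(2016L, 2021L)) {
    records$lives_with_smoker[routed] <- NA_character_
  }
  records
}

#' Harmonize a participant table to the shared schema
#'
#' Validates columns and category labels against the data dictionary,
#' applies the age recode where needed, namespaces school identifiers by
#' source, and (idempotently) returns a table in canonical column order.
#' In strict mode unknown category labels are an error; in lenient mode they
#' are set to missing with a warning.
#'
#' @param records data.frame with the columns of [data_dictionary()].
#' @param strict reject unknown category labels instead of coding them
#'   missing.
#' @return harmonized data.frame; the number of rows is always preserved.
#' @export
harmonize_records <- function(records, strict = TRUE) {
  missing_cols <- setdiff(.participant_columns, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n_in <- nrow(records)
  records <- records[, .participant_columns]
  records$age <- recode_age(as.integer(records$age))
  for (v in names(.covariate_levels)) {
    if (v == "age") next
    lv <- .covariate_levels[[v]]
    x <- as.character(records[[v]])
    bad <- !is.na(x) & !x %in% lv
    if (any(bad)) {
      if (strict) {
        stop("unknown level(s) in ", v, ": ",
             paste(unique(x[bad]), collapse = ", "))
      }
      warning(sum(bad), " unknown label(s) in ", v, " coded as missing")
      x[bad] <- NA_character_
    }
    records[[v]] <- x
  }
  bad_src <- !records$source %in% c("trial", "target")
  if (any(bad_src)) stop("source must be 'trial' or 'target'")
  # namespace school ids by source so trial and survey schools never pool
  pref <- ifelse(records$source == "trial", "trial:", "target:")
  need <- !startsWith(records$school_id, "trial") &
    !startsWith(records$school_id, "target") &
    !startsWith(records$school_id, "survey")
  records$school_id[need] <- paste0(pref[need], records$school_id[need])
  is_target <- records$source == "target"
  records$arm[is_target] <- NA_character_
  records$outcome_weekly[is_target] <- NA_integer_
  records$outcome_weekly <- as.integer(records$outcome_weekly)
  stopifnot(nrow(records) == n_in)  # no silent drops, ever
  records
}

#' Stack a trial dataset with one target-population survey
#'
#' Appends the survey records below the trial records and adds the selection
#' indicator `S` (1 = trial, 0 = target).  Trial rows always come first and
#' row counts are conserved.
#'
#' @param trial harmonized trial records.
#' @param target harmonized survey records for one year.
#' @param year the survey year (defaults to the year on the target records).
#' @return an object of class `stacked_data`: the combined data.frame with
#'   columns `S` and `year_stacked`, plus attributes `n_trial`, `n_target`.
#' @export
stack_datasets <- function(trial, target, year = NULL) {
  if (is.null(target) || nrow(target) == 0) {
    stop("target dataset is empty: nothing to transport to")
  }
  if (is.null(trial) || nrow(trial) == 0) stop("trial dataset is empty")
  if (!identical(sort(names(trial)), sort(names(target)))) {
    stop("schema mismatch between trial and target records")
  }
  if (!all(trial$source == "trial")) stop("trial records must have source 'trial'")
  if (!all(target$source == "target")) stop("target records must have source 'target'")
  if (length(intersect(unique(trial$school_id), unique(target$school_id)))) {
    stop("school ids overlap across sources; namespace them via harmonize_records()")
  }
  year <- as.integer(year %||% target$year[1])
  out <- rbind(trial[, .participant_columns], target[, .participant_columns])
  out$S <- rep(c(1L, 0L), c(nrow(trial), nrow(target)))
  out$year_stacked <- year
  structure(out, n_trial = nrow(trial), n_target = nrow(target),
            class = c("stacked_data", "data.frame"))
}

#' @export
print.stacked_data <- function(x, ...) {
  cat(sprintf("Stacked dataset: %d trial + %d target records (year %d)\n",
              attr(x, "n_trial"), attr(x, "n_target"), x$year_stacked[1]))
  invisible(x)
}

#' Read / write harmonized participant tables as CSV
#'
#' The CSV layout follows [data_dictionary()].  Reading validates labels
#' (strict by default) and re-harmonizes, so a round trip is the identity.
#'
#' @param records harmonized participant data.frame.
#' @param path file path.
#' @param strict passed to [harmonize_records()].
#' @return `read_participants` returns the data.frame; `write_participants`
#'   returns `path` invisibly.
#' @export
write_participants <- function(records, path) {
  utils::write.csv(records[, .participant_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  raw$year <- as.integer(raw$year)
  raw$age <- as.integer(raw$age)
  raw$outcome_weekly <- as.integer(raw$outcome_weekly)
  harmonize_records(raw, strict = strict)
}
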