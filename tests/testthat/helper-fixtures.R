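# Shared fixtures, memoised so expensive simulations run once per session.

tt_cache <- new.env(parent = emptyenv())

tt_memo <- function(key, expr) {
  if (!exists(key, envir = tt_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = tt_cache)
  }
  get(key, envir = tt_cache, inherits = FALSE)
}

tt_quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# small trial + surveys: ~1500 trial records, 24 schools (enough clusters
# for a stable school-level sandwich)
tt_cfg_small <- function() tt_memo("cfg_small", {
  cfg <- scale_config(make_default_config(), 6)
  cfg$trial$arm_schools <- c(control = 12L, intervention = 12L)
  cfg$trial$n_schools <- 24L
  for (y in names(cfg$surveys)) cfg$surveys[[y]]$n_schools <- 15L
  validate_config(cfg)
  cfg
})

tt_trial_small <- function() tt_memo("trial_small", generate_trial(tt_cfg_small(), seed = 3))

tt_survey_small <- function(year) {
  tt_memo(paste0("survey_small_", year),
          generate_survey(tt_cfg_small(), year, seed = 3))
}

tt_stacked_small <- function(year = 2004) {
  tt_memo(paste0("stacked_small_", year),
          stack_datasets(tt_trial_small(), tt_survey_small(year)))
}

tt_weights_small <- function(year = 2004) {
  tt_memo(paste0("weights_small_", year), {
    sel <- tt_quiet(fit_selection_model(tt_stacked_small(year)))
    keep <- transportable_mask(sel, tt_trial_small())
    inverse_odds_weights(
      predict_selection_prob(sel, tt_trial_small()[keep, , drop = FALSE]))
  })
}

# config whose single survey shares the trial's covariate distribution
# (exchangeable populations)
tt_cfg_equal <- function(n = 2000L, n_schools = 20L) {
  cfg <- make_default_config()
  cfg$trial$arm_schools <- c(control = n_schools %/% 2L,
                             intervention = n_schools - n_schools %/% 2L)
  cfg$trial$n_schools <- n_schools
  cfg$trial$arm_students <- c(control = n %/% 2L, intervention = n - n %/% 2L)
  cfg$surveys <- list(`2004` = list(year = 2004L, n_students = n,
                                    n_schools = n_schools,
                                    marginals = cfg$trial$marginals))
  validate_config(cfg)
  cfg
}

# absolute-tolerance comparison (expect_equal's tolerance is relative)
tt_expect_close <- function(actual, expected, tol, label = "value") {
  testthat::expect(
    isTRUE(abs(actual - expected) <= tol),
    sprintf("%s: |%.6g - %.6g| = %.3g exceeds %.3g",
            label, actual, expected, abs(actual - expected), tol)
  )
  invisible(actual)
}

# interpolate survey marginals between the trial and a reference survey year
tt_mix_marginals <- function(m_from, m_to, s) {
  out <- m_from
  for (v in names(out)) out[[v]] <- (1 - s) * m_from[[v]] + s * m_to[[v]]
  out
}
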