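test_that("trial schools get exact arm counts by stratified randomization", {
  cfg <- make_default_config()
  sch <- generate_schools(cfg, "trial", seed = 5)
  expect_equal(nrow(sch), 59L)
  expect_equal(sum(sch$arm == "intervention"), 30L)
  expect_equal(sum(sch$arm == "control"), 29L)
  expect_identical(sch, generate_schools(cfg, "trial", seed = 5))
  expect_false(identical(sch$arm, generate_schools(cfg, "trial", seed = 6)$arm))
})

test_that("block randomization balances arms within a single stratum", {
  cfg <- make_default_config()
  # degenerate strata: every school in the same stratum
  for (s in names(cfg$strata)) {
    cfg$strata[[s]] <- stats::setNames(c(1, 0), names(cfg$strata[[s]]))
  }
  cfg$trial$n_schools <- 4L
  cfg$trial$arm_schools <- c(control = 2L, intervention = 2L)
  for (seed in 1:5) {
    sch <- generate_schools(cfg, "trial", seed = seed)
    expect_equal(unname(table(sch$arm)["control"]), 2L)
    expect_equal(unname(table(sch$arm)["intervention"]), 2L)
  }
  cfg$trial$arm_schools <- c(control = 2L, intervention = 3L)
  expect_error(generate_schools(cfg, "trial"), "sum|exceed")
})

test_that("intercept calibration matches closed forms and Monte Carlo integration", {
  m <- make_default_config()$trial$marginals
  zero <- lapply(m, function(p) stats::setNames(rep(0, length(p)), names(p)))
  expect_equal(solve_intercept(0.5, m, zero, 0), 0, tolerance = 1e-8)
  a <- solve_intercept(0.041, m, zero, 0)
  expect_equal(a, stats::qlogis(0.041), tolerance = 1e-8)
  # with clustering the intercept must shift below the plain logit (Jensen)
  a1 <- solve_intercept(0.041, m, zero, 1)
  expect_lt(a1, a)
  # brute-force Monte Carlo integration over the random intercept as oracle
  set.seed(42)
  u <- stats::rnorm(4e5, 0, 1)
  tt_expect_close(mean(stats::plogis(a1 + u)), 0.041, 3 * 2e-4)
  # covariate effects: plug-back check via large simulated population
  cfg <- make_default_config(sigma_u = 0.5)
  om <- cfg$outcome_model
  a2 <- solve_intercept(0.1, cfg$trial$marginals, om$coefs, 0.5)
  set.seed(7)
  n <- 2e5
  school <- sample.int(400, n, replace = TRUE)
  cov <- trialtransport:::sample_covariates(n, cfg$trial$marginals,
                                            school, hook = TRUE)
  eta <- a2 + stats::rnorm(400, 0, 0.5)[school]
  for (v in covariate_names()) eta <- eta + om$coefs[[v]][as.character(cov[[v]])]
  tt_expect_close(mean(stats::plogis(unname(eta))), 0.1,
                  3 * sqrt(0.1 * 0.9 / n) + 2e-3)
  expect_error(solve_intercept(1.2, m, zero, 0), "target")
})

test_that("generated trial matches the configured design exactly", {
  cfg <- make_default_config()
  tr <- tt_memo("trial_full", generate_trial(cfg, seed = 1))
  expect_equal(nrow(tr), 8756L)
  expect_equal(length(unique(tr$school_id)), 59L)
  expect_equal(sum(tr$arm == "intervention"), 4563L)
  expect_equal(sum(tr$arm == "control"), 4193L)
  expect_true(all(tr$source == "trial"))
  expect_true(all(tr$outcome_weekly %in% 0:1))
  # consistency hook: never-smokers never report an age at first cigarette
  expect_true(all(tr$age_first_cig[tr$smoking_status == "never"] == "never"))
  expect_identical(tr, generate_trial(cfg, seed = 1))
})

test_that("realized covariate marginals converge to the configured marginals", {
  cfg <- make_default_config()
  sv <- tt_memo("survey_2004_large",
                generate_survey(cfg, 2004, seed = 2, n_students = 1e5))
  m <- cfg$surveys[["2004"]]$marginals
  for (v in c("gender", "ethnicity", "smoking_status", "lives_with_smoker")) {
    for (l in names(m[[v]])) {
      p <- m[[v]][[l]]
      se <- sqrt(p * (1 - p) / 1e5)
      tt_expect_close(mean(as.character(sv[[v]]) == l), p, 3 * se + 1e-12,
                      label = paste(v, l))
    }
  }
})

test_that("trial outcome prevalence is calibrated to its target", {
  cfg <- make_default_config()
  prev <- vapply(1:20, function(s) mean(generate_trial(cfg, seed = s)$outcome_weekly), 0)
  mc_se <- stats::sd(prev) / sqrt(length(prev))
  tt_expect_close(mean(prev), cfg$outcome_model$target_prevalence, 3 * mc_se)
})

test_that("a null intervention effect gives symmetric arm prevalences", {
  cfg <- make_default_config(treatment_log_or = 0, sigma_u = 0)
  cfg$trial$arm_students <- c(control = 20000L, intervention = 20000L)
  tr <- generate_trial(cfg, seed = 8)
  p1 <- mean(tr$outcome_weekly[tr$arm == "intervention"])
  p0 <- mean(tr$outcome_weekly[tr$arm == "control"])
  tt_expect_close(p1, p0, 3 * sqrt(2 * 0.041 * 0.959 / 20000))
})

test_that("surveys have the published sizes, no arm and no outcome", {
  cfg <- make_default_config()
  sv04 <- generate_survey(cfg, 2004, seed = 1)
  sv16 <- generate_survey(cfg, 2016, seed = 1)
  expect_equal(nrow(sv04), 3958L)
  expect_equal(nrow(sv16), 4874L)
  expect_true(all(is.na(sv04$arm)))
  expect_true(all(is.na(sv04$outcome_weekly)))
  expect_true("weekly" %in% sv04$smoking_status)
  expect_identical(sv04, generate_survey(cfg, 2004, seed = 1))
  expect_error(generate_survey(cfg, 1999), "unknown survey year")
})

test_that("ground-truth estimand is the configured effect under homogeneity", {
  cfg <- make_default_config()
  for (y in c(2004, 2021)) {
    te <- true_transported_estimand(cfg, y)
    expect_identical(te$method, "analytic")
    expect_identical(te$estimand, log(0.85))
  }
  expect_identical(true_transported_estimand(make_default_config(treatment_log_or = 0),
                                             2004)$estimand, 0)
})

test_that("effect modification attenuates the transported estimand", {
  # the whole effect sits in ever-smokers; 2021 has far fewer of them than
  # 2004, so the target-population arm coefficient must shrink toward zero
  cfg <- make_default_config(
    treatment_log_or = 0,
    interactions = list(smoking_status = c(never = 0, occ_exp_ex = -0.5,
                                           weekly = -0.5)))
  te21 <- true_transported_estimand(cfg, 2021, n_sim = 40000L, seed = 2)
  te04 <- true_transported_estimand(cfg, 2004, n_sim = 40000L, seed = 2)
  expect_identical(te21$method, "brute_force")
  expect_lt(abs(te21$estimand), abs(te04$estimand))
  expect_lt(abs(te21$estimand), 0.5)
})
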