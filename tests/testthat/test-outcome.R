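tt_one_school_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  dat <- data.frame(
    source = "trial", year = 2004L, school_id = "trial:s001",
    arm = rep(c("intervention", "control"), c(a + b, c_ + d)),
    gender = "boy", age = 12L, ethnicity = "white",
    smoking_status = "never", age_first_cig = "never",
    lives_with_smoker = "yes", lesson_smoking = "yes",
    outcome_weekly = c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d)),
    stringsAsFactors = FALSE
  )
  for (s in stratification_names(TRUE)) dat[[s]] <- "england"
  dat
}

test_that("confidence interval ratio reproduces its definition", {
  expect_equal(round(ci_ratio(0.72, 1.13), 2), 1.57)
  expect_equal(ci_ratio(2, 2), 1)
  expect_equal(ci_ratio(0.5, 2.0), 4.0)
  expect_error(ci_ratio(-1, 2), "positive")
  expect_error(ci_ratio(0, 2), "positive")
  expect_error(ci_ratio(2, 1), ">=")
})

test_that("a no-covariate single-school weighted fit equals the cross-product ratio", {
  dat <- tt_one_school_2x2(10, 90, 20, 80)
  est <- tt_quiet(fit_transported_effect(dat, rep(1, 200), strat_vars = character(0)))
  expect_equal(est$or_, (10 * 80) / (90 * 20), tolerance = 1e-5)
  expect_equal(est$n, 200L)
})

test_that("unit weights reproduce the unweighted trial fit exactly", {
  tr <- tt_trial_small()
  e0 <- tt_quiet(fit_trial_effect(tr))
  e1 <- tt_quiet(fit_transported_effect(tr, rep(1, nrow(tr))))
  expect_equal(e1$log_or, e0$log_or, tolerance = 1e-8)
  expect_true(e1$weighted)
  expect_false(e0$weighted)
  expect_error(fit_transported_effect(tr, rep(1, 5)), "misaligned")
  expect_error(fit_transported_effect(tr, rep(-1, nrow(tr))), "positive")
})

test_that("integer weights equal the fit on row-replicated data", {
  tr <- tt_trial_small()
  set.seed(12)
  k <- sample(1:3, nrow(tr), replace = TRUE)
  e_w <- tt_quiet(fit_transported_effect(tr, k, rescale_weights = FALSE,
                                         strat_vars = character(0)))
  e_rep <- tt_quiet(fit_trial_effect(tr[rep(seq_len(nrow(tr)), k), ],
                                     strat_vars = character(0)))
  tt_expect_close(e_w$log_or, e_rep$log_or, 1e-4)
})

test_that("point estimates and sandwich SEs are invariant to the weight scale", {
  tr <- tt_trial_small()
  ws <- tt_weights_small()
  e1 <- tt_quiet(fit_transported_effect(tr, ws$weights))
  e2 <- tt_quiet(fit_transported_effect(tr, 5 * ws$weights))
  tt_expect_close(e1$log_or, e2$log_or, 1e-5)
  tt_expect_close(e1$se, e2$se, 1e-3)
})

test_that("relabelling the outcome inverts the OR and preserves the CI ratio", {
  tr <- tt_trial_small()
  ws <- tt_weights_small()
  e <- tt_quiet(fit_transported_effect(tr, ws$weights))
  flipped <- tr
  flipped$outcome_weekly <- 1L - flipped$outcome_weekly
  ef <- tt_quiet(fit_transported_effect(flipped, ws$weights))
  tt_expect_close(ef$log_or, -e$log_or, 5e-3)
  tt_expect_close(ef$ci_ratio, e$ci_ratio, 0.02 * e$ci_ratio)
})

test_that("the trial fit recovers the generating intervention effect", {
  cfg <- make_default_config()
  cfg$trial$arm_schools <- c(control = 50L, intervention = 50L)
  cfg$trial$n_schools <- 100L
  cfg$trial$arm_students <- c(control = 10000L, intervention = 10000L)
  tr <- generate_trial(cfg, seed = 41)
  est <- tt_quiet(fit_trial_effect(tr))
  tt_expect_close(est$log_or, log(0.85), 3 * est$se)
  expect_equal(est$or_, exp(est$log_or))
  expect_true(est$ci_low < est$or_ && est$or_ < est$ci_high)
  expect_gte(est$ci_ratio, 1)
})

test_that("permuting arm labels at school level centres the OR on 1", {
  tr <- tt_trial_small()
  schools <- unique(tr[c("school_id", "arm")])
  lo <- numeric(12)
  set.seed(77)
  for (b in seq_along(lo)) {
    perm <- stats::setNames(sample(schools$arm), schools$school_id)
    trb <- tr
    trb$arm <- unname(perm[trb$school_id])
    lo[b] <- tt_quiet(fit_trial_effect(trb, strat_vars = character(0)))$log_or
  }
  expect_lte(abs(mean(lo)), 3 * stats::sd(lo) / sqrt(length(lo)))
})

test_that("an outcome constant within an arm is an explicit error", {
  dat <- tt_one_school_2x2(10, 90, 20, 80)
  dat$outcome_weekly[dat$arm == "control"] <- 0L
  expect_error(tt_quiet(fit_trial_effect(dat, strat_vars = character(0))),
               "constant within arm")
})

test_that("forest tables flatten estimate lists", {
  tr <- tt_trial_small()
  e0 <- tt_quiet(fit_trial_effect(tr))
  ft <- forest_table(list(e0))
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$or_, e0$or_)
  expect_equal(ft$ci_ratio, e0$ci_ratio)
})
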