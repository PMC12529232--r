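test_that("amputation imposes the requested missingness mechanisms", {
  tr <- tt_trial_small()
  amp0 <- amputate(tr, list(lesson_smoking = list(rate = 0)), seed = 1)
  expect_equal(as.data.frame(amp0), tr, ignore_attr = TRUE)
  big <- tt_memo("trial_mcar_base", {
    cfg <- tt_cfg_equal(n = 10000L)
    generate_trial(cfg, seed = 51)
  })
  amp <- amputate(big, list(lesson_smoking = list(rate = 0.2)), seed = 2)
  tt_expect_close(mean(is.na(amp$lesson_smoking)), 0.2,
                  3 * sqrt(0.2 * 0.8 / nrow(big)))
  # MAR driven by gender: realized log-odds gap matches the mechanism
  amp_mar <- amputate(big, list(
    lives_with_smoker = list(rate = 0.25,
                             predictors = list(gender = c(girl = 1)))), seed = 3)
  miss <- is.na(amp_mar$lives_with_smoker)
  lo_gap <- stats::qlogis(mean(miss[big$gender == "girl"])) -
    stats::qlogis(mean(miss[big$gender == "boy"]))
  tt_expect_close(lo_gap, 1, 0.25)
  tt_expect_close(mean(miss), 0.25, 3 * sqrt(0.25 * 0.75 / nrow(big)))
  # original values retained for recovery testing
  expect_identical(attr(amp, "truth")$lesson_smoking, big$lesson_smoking)
  expect_error(amputate(big, list(gender = list(rate = 0.1,
    predictors = list(gender = c(girl = 1))))), "MNAR")
})

test_that("missingness diagnostic recovers the amputation mechanism", {
  big <- tt_memo("trial_mcar_base", {
    cfg <- tt_cfg_equal(n = 10000L)
    generate_trial(cfg, seed = 51)
  })
  # MCAR: no covariate predicts missingness
  amp <- amputate(big, list(lesson_smoking = list(rate = 0.2)), seed = 4)
  diag_mcar <- tt_quiet(missingness_diagnostic(amp, "lesson_smoking"))
  cf <- diag_mcar$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  expect_true(all(abs(cf$estimate) <= 3.5 * cf$se))
  # MAR on gender: the gender coefficient recovers the mechanism log-odds
  amp_mar <- amputate(big, list(
    lesson_smoking = list(rate = 0.2,
                          predictors = list(gender = c(girl = 1)))), seed = 5)
  diag_mar <- tt_quiet(missingness_diagnostic(amp_mar, "lesson_smoking"))
  g <- diag_mar$coefficients[diag_mar$coefficients$term == "gendergirl", ]
  tt_expect_close(g$estimate, 1, 3 * g$se)
  expect_error(missingness_diagnostic(big, "lesson_smoking"), "fully observed")
})

test_that("imputation is the identity on complete data and is seed-stable", {
  tr <- tt_trial_small()
  imp <- impute(tr, m = 3, seed = 7)
  for (d in imp$completed_datasets) expect_identical(d, as.data.frame(tr))
  amp <- amputate(tr, list(lesson_smoking = list(rate = 0.15)), seed = 8)
  i1 <- impute(amp, m = 2, seed = 9)
  i2 <- impute(amp, m = 2, seed = 9)
  expect_identical(i1$completed_datasets, i2$completed_datasets)
  expect_false(identical(i1$completed_datasets[[1]],
                         impute(amp, m = 2, seed = 10)$completed_datasets[[1]]))
  expect_error(impute(amp, m = 1), "at least 2")
})

test_that("chained-equations imputation preserves observed cells and MCAR marginals", {
  big <- tt_memo("trial_mcar_base", {
    cfg <- tt_cfg_equal(n = 10000L)
    generate_trial(cfg, seed = 51)
  })[1:4000, ]
  amp <- amputate(big, list(lives_with_smoker = list(rate = 0.2)), seed = 11)
  imp <- impute(amp, m = 4, seed = 12, cycles = 5)
  obs_idx <- which(!is.na(amp$lives_with_smoker))
  p_obs <- mean(amp$lives_with_smoker[obs_idx] == "yes")
  for (d in imp$completed_datasets) {
    expect_false(anyNA(d$lives_with_smoker))
    # observed cells untouched
    expect_identical(d$lives_with_smoker[obs_idx],
                     amp$lives_with_smoker[obs_idx])
  }
  p_imp <- mean(vapply(imp$completed_datasets,
                       function(d) mean(d$lives_with_smoker == "yes"), 0))
  tt_expect_close(p_imp, p_obs, 0.03)
})

test_that("joint-normal imputation also completes the data", {
  tr <- tt_trial_small()
  amp <- amputate(tr, list(lesson_smoking = list(rate = 0.15),
                           lives_with_smoker = list(rate = 0.1)), seed = 13)
  imp <- impute(amp, m = 2, seed = 14, method = "multivariate_normal")
  for (d in imp$completed_datasets) {
    expect_false(anyNA(d$lesson_smoking))
    expect_false(anyNA(d$lives_with_smoker))
    expect_true(all(d$lesson_smoking %in% variable_levels("lesson_smoking")))
  }
  expect_identical(imp$method, "multivariate_normal")
})

test_that("Rubin's rules match hand-computed pooling", {
  pl <- pool_rubin(c(0.1, 0.2, 0.3), c(0.04, 0.04, 0.04))
  expect_equal(pl$qbar, 0.2)
  expect_equal(pl$W, 0.04)
  expect_equal(pl$B, 0.01)
  expect_equal(pl$T, 0.04 + (4 / 3) * 0.01)
  expect_equal(pl$mcse, sqrt(0.01 / 3))
  # degenerate: identical estimates collapse to the single-fit answer
  pl0 <- pool_rubin(c(0.5, 0.5), c(1, 1))
  expect_equal(pl0$qbar, 0.5)
  expect_equal(pl0$B, 0)
  expect_equal(pl0$T, 1)
  expect_equal(pl0$mcse, 0)
  expect_identical(pl0$df, Inf)
  expect_gte(pl$T, pl$W)
  expect_error(pool_rubin(0.1, 0.04), "at least 2")
  expect_error(pool_rubin(c(0.1, 0.2), c(0.04, -1)), "positive")
  # Barnard-Rubin df shrinks with finite complete-data df
  expect_lt(pool_rubin(c(0.1, 0.2, 0.3), c(0.04, 0.04, 0.04),
                       df_complete = 50)$df, pl$df)
})

test_that("Monte Carlo error check flags unstable pooling", {
  expect_false(monte_carlo_error_check(pool_rubin(c(0.5, 0.5), c(1, 1)))$flag)
  noisy <- pool_rubin(c(-1, 1, -1, 1), rep(0.01, 4))
  expect_true(monte_carlo_error_check(noisy)$flag)
  # more imputations reduce the Monte Carlo error on the same problem
  set.seed(15)
  q <- stats::rnorm(40, 0, 0.3)
  m1 <- monte_carlo_error_check(pool_rubin(q[1:10], rep(0.04, 10)))$mcse
  m2 <- monte_carlo_error_check(pool_rubin(q, rep(0.04, 40)))$mcse
  expect_lt(m2, m1)
})
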