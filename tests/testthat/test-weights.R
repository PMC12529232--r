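# helper: a minimal stacked dataset with hand-set covariates
tt_hand_stacked <- function(gender_trial, gender_target, n_schools = 4L) {
  mk <- function(gender, source, prefix) {
    n <- length(gender)
    d <- data.frame(
      source = source, year = 2004L,
      school_id = paste0(prefix, ":s", rep_len(seq_len(n_schools), n)),
      arm = if (source == "trial")
        rep_len(c("control", "intervention"), n) else NA_character_,
      gender = gender, age = 12L, ethnicity = "white",
      smoking_status = "never", age_first_cig = "never",
      lives_with_smoker = "yes", lesson_smoking = "yes",
      outcome_weekly = if (source == "trial") rep_len(0:1, n) else NA_integer_,
      stringsAsFactors = FALSE
    )
    for (s in stratification_names(TRUE)) d[[s]] <- "england"
    d$strat_country <- "england"
    d
  }
  stack_datasets(mk(gender_trial, "trial", "trial"),
                 mk(gender_target, "target", "survey"))
}

test_that("selection coefficient matches the closed-form 2x2 logistic MLE", {
  # trial: 300 boys / 100 girls; target: 100 boys / 300 girls
  st <- tt_hand_stacked(rep(c("boy", "girl"), c(300, 100)),
                        rep(c("boy", "girl"), c(100, 300)))
  sel <- tt_quiet(fit_selection_model(st, covariates = "gender"))
  expect_equal(unname(sel$coefficients[["gendergirl"]]),
               log((100 * 100) / (300 * 300)), tolerance = 1e-6)
  expect_equal(sel$intercept, log(300 / 100), tolerance = 1e-6)
  expect_equal(sel$random_intercept_sd, 0)
  expect_true(sel$converged)
})

test_that("exchangeable populations give null selection coefficients and flat weights", {
  cfg <- tt_cfg_equal(n = 2500L)
  tr <- tt_memo("eq_trial", generate_trial(cfg, seed = 21))
  sv <- tt_memo("eq_survey", generate_survey(cfg, 2004, seed = 22))
  st <- stack_datasets(tr, sv)
  sel <- tt_quiet(fit_selection_model(st))
  sm <- summary(sel$model)$coefficients
  covs <- rownames(sm)[rownames(sm) != "(Intercept)"]
  expect_true(all(abs(sm[covs, "Estimate"]) <= 3 * sm[covs, "Std. Error"]))
  tt_expect_close(sel$intercept, stats::qlogis(nrow(tr) / nrow(st)),
                  3 * sm["(Intercept)", "Std. Error"])
  p <- predict_selection_prob(sel, tr)
  ws <- inverse_odds_weights(p)
  # weights concentrate near n_target / n_trial
  tt_expect_close(stats::median(ws$weights), nrow(sv) / nrow(tr), 0.1)
  expect_gt(ws$ess, 0.9 * nrow(tr))
  # weighted covariate means stay at the unweighted means
  for (v in c("gender", "smoking_status", "age")) {
    x <- as.character(tr[[v]])
    for (l in unique(x)) {
      tt_expect_close(stats::weighted.mean(x == l, ws$weights), mean(x == l),
                      0.05, label = paste(v, l))
    }
  }
})

test_that("a covariate level present in only one population is a positivity error", {
  st <- tt_hand_stacked(rep("boy", 200), rep(c("boy", "girl"), c(100, 100)))
  expect_error(tt_quiet(fit_selection_model(st, covariates = "gender")),
               "positivity")
})

test_that("selection probabilities respect closed forms and quadrature", {
  st <- tt_hand_stacked(rep(c("boy", "girl"), c(200, 200)),
                        rep(c("boy", "girl"), c(200, 200)))
  sel <- tt_quiet(fit_selection_model(st, covariates = "gender"))
  p <- predict_selection_prob(sel, as.data.frame(st)[st$S == 1, ])
  expect_equal(unname(p), rep(0.5, 400), tolerance = 1e-6)
  # marginal integration: quadrature against brute-force Monte Carlo
  eta <- stats::qlogis(0.2)
  p_quad <- trialtransport:::marginal_expit(eta, 1)
  set.seed(99)
  p_mc <- mean(stats::plogis(eta + stats::rnorm(2e6)))
  expect_equal(p_quad, p_mc, tolerance = 1e-3)
  expect_equal(trialtransport:::marginal_expit(eta, 0), 0.2, tolerance = 1e-12)
  # more nodes does not move the quadrature answer
  gh61 <- trialtransport:::gauss_hermite_normal(61L)
  p61 <- sum(gh61$weights * stats::plogis(eta + gh61$nodes))
  expect_equal(p_quad, p61, tolerance = 1e-7)
})

test_that("inverse odds weights follow (1-p)/p with sane diagnostics", {
  ws <- inverse_odds_weights(c(0.5, 0.2))
  expect_equal(ws$weights, c(1, 4))
  expect_error(inverse_odds_weights(c(0.5, 1)), "positivity")
  expect_error(inverse_odds_weights(c(0, 0.5)), "positivity")
  expect_equal(effective_sample_size(rep(2, 10)), 10)
  expect_lt(effective_sample_size(c(rep(1, 9), 100)), 10)
  wn <- inverse_odds_weights(c(0.5, 0.2), normalize = TRUE)
  expect_equal(mean(wn$weights), 1)
  wt <- inverse_odds_weights(seq(0.05, 0.95, by = 0.05), truncate = c(0.1, 0.9))
  expect_lte(max(wt$weights), max(inverse_odds_weights(seq(0.05, 0.95, by = 0.05))$weights))
})

test_that("true inverse-odds weights recover the target covariate distribution", {
  # generator-known weights: w(x) proportional to f_target(x) / f_trial(x)
  cfg <- make_default_config()
  cfg$trial$arm_students <- c(control = 25000L, intervention = 25000L)
  tr <- generate_trial(cfg, seed = 31)
  m_tr <- cfg$trial$marginals
  m_tg <- cfg$surveys[["2004"]]$marginals
  j_tr <- trialtransport:::smoking_agefirst_joint(m_tr, TRUE)
  j_tg <- trialtransport:::smoking_agefirst_joint(m_tg, TRUE)
  idx <- cbind(as.character(tr$smoking_status), as.character(tr$age_first_cig))
  w <- j_tg[idx] / j_tr[idx]
  for (v in setdiff(covariate_names(), c("smoking_status", "age_first_cig"))) {
    x <- as.character(tr[[v]])
    w <- w * m_tg[[v]][x] / m_tr[[v]][x]
  }
  w <- unname(w)
  # under the consistency hook the generator realizes the hook-adjusted
  # joint for (smoking status, age first); compare against its margins
  m_expect <- m_tg
  m_expect$smoking_status <- rowSums(j_tg)
  m_expect$age_first_cig <- colSums(j_tg)
  for (v in covariate_names()) {
    x <- as.character(tr[[v]])
    for (l in names(m_expect[[v]])) {
      p <- m_expect[[v]][[l]]
      mc_se <- sqrt(p * (1 - p) * sum(w^2)) / sum(w)
      tt_expect_close(stats::weighted.mean(x == l, w), p,
                      3 * mc_se + 0.005, label = paste(v, l))
    }
  }
})

test_that("positivity report flags target-only cells and tracks covariate shift", {
  ws <- tt_weights_small()
  st <- tt_stacked_small()
  rep_ok <- positivity_report(ws, st)
  expect_true(rep_ok$ok)
  expect_lte(rep_ok$ess, length(ws$weights))
  # inject a target-only covariate cell: all girls removed from the trial arm
  dat <- as.data.frame(st)
  dat$gender[dat$S == 1 & dat$arm == "intervention" & dat$gender == "girl"] <- "boy"
  st2 <- stack_datasets(dat[dat$S == 1, names(dat) != "S" &
                              names(dat) != "year_stacked"],
                        dat[dat$S == 0, names(dat) != "S" &
                              names(dat) != "year_stacked"])
  rep_bad <- positivity_report(ws, st2)
  expect_false(rep_bad$ok)
  expect_true(any(rep_bad$flagged_cells$covariate == "gender" &
                  rep_bad$flagged_cells$level == "girl" &
                  rep_bad$flagged_cells$arm == "intervention"))
  # stronger covariate shift degrades the effective sample size
  ess_mild <- tt_weights_small(2004)$ess
  ess_strong <- tt_weights_small(2021)$ess
  expect_lt(ess_strong, ess_mild)
})
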