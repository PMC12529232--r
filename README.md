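# trialtransport

Transporting a cluster-randomized trial's intervention effect to external
target populations observed at several time points, by inverse odds of
selection weighting.

## The problem

Trials estimate effects in their own samples; commissioners need effects in
*their* populations, often years later. This package implements the
transportability pipeline for a school-based smoking-prevention
cluster-RCT (59 schools, 8756 students aged 12–13, binary weekly-smoking
outcome at a two-year follow-up) and a series of national school surveys
standing in for the target population in 2004, 2006, 2014, 2016 and 2021.
It is written for applied biostatisticians and trialists who want a tested,
reproducible implementation of the whole chain: harmonization, stacking,
selection modelling, weighting with positivity diagnostics, weighted
multilevel outcome estimation, multiple imputation, and reporting.

Because the underlying trial and survey microdata are access-restricted,
the package includes a first-class synthetic-data generator calibrated to
the published sample sizes and covariate margins, with known ground-truth
effects, so the estimator can be validated by parameter recovery.

## The method

With $S = 1$ for trial membership and $S = 0$ for the target, stack the two
sources, fit a logistic selection model $P(S = 1 \mid X)$ on harmonized
covariates $X$ (gender, age, ethnicity, smoking status, age at first
cigarette, residence with a smoker, lesson on smoking), and weight each
trial participant by the inverse of their selection odds,

$$w_i = \frac{1 - p_i}{p_i}, \qquad p_i = \widehat P(S_i = 1 \mid X_i).$$

The weighted trial then resembles the target population. The transported
intention-to-treat effect is the arm coefficient of a weighted school
random-intercept logistic model of weekly smoking, adjusted for the six
school-level randomization stratification variables, with a school-level
cluster-robust sandwich variance:

$$\operatorname{logit} P(Y_{ij} = 1) = \alpha + \beta_A A_j + \gamma' Z_j + u_j,
\qquad u_j \sim N(0, \sigma_u^2),$$

reported as an odds ratio with a 95% Wald interval. Precision is tracked by
the confidence interval ratio (upper limit / lower limit), which grows as
the trial and target drift apart. Missing values are handled by multiple
imputation (chained equations, m = 20 by default) with Rubin's-rules
pooling, a Barnard–Rubin degrees-of-freedom correction and a Monte Carlo
error check; complete-case and England-only sensitivity analyses are one
flag each.

## Worked example

Generate a reduced synthetic bundle (about 1500 trial records in 24
schools) and transport the trial effect to two survey years:

```r
library(trialtransport)

cfg <- scale_config(make_default_config(), 6)
cfg$trial$arm_schools <- c(control = 12L, intervention = 12L)
cfg$trial$n_schools <- 24L

trial   <- generate_trial(cfg, seed = 1)
surveys <- list(`2004` = generate_survey(cfg, 2004, seed = 1),
                `2016` = generate_survey(cfg, 2016, seed = 1))

report <- run_transport(trial, surveys, analysis_config(m = 2, seed = 1))
report
#> Transport analysis report
#>   Trial-population trial effect: OR 1.091 (95% CI 0.631-1.884), CI ratio 2.98, n = 1459 in 24 schools
#>   Transported year 2004 effect: OR 1.841 (95% CI 0.702-4.829), CI ratio 6.88, n = 1459 in 24 schools
#>   Transported year 2016 effect: OR 0.603 (95% CI 0.068-5.350), CI ratio 78.75, n = 1459 in 24 schools
```

Reading the output: the unweighted trial estimate is the usual multilevel
trial analysis. Each transported line reweights the same trial students to
one survey year's covariate mix; at this reduced size the true effect
(OR 0.85) is well inside every interval, and the intervals widen sharply
with the covariate shift — the effective sample size falls from 841 (2004
weights) to 379 (2016 weights) of 1459 trial records, and the CI ratio
rises from 6.9 to 78.8. That widening-with-drift pattern is the package's
central diagnostic; at the full published scale the generator reproduces
the trial's 4.1% weekly smoking, 49.5% girls and the survey drift down to
0.2% weekly smoking in 2021.

`write_report(report, "out/")` writes a JSON report and a forest-table CSV
(year, OR, confidence limits, CI ratio). `make_fixture_bundle("data/",
seed = 1)` writes the full-size calibrated CSV bundle plus a YAML config.
A thin command-line front end lives in `inst/scripts/transport_cli.R`
(subcommands `simulate` and `transport`).

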