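---
title: "Transporting a cluster-trial effect to serial survey populations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transporting a cluster-trial effect to serial survey populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A school-based smoking-prevention intervention was evaluated in a two-arm
cluster-randomized trial: 59 secondary schools (30 intervention, 29 control;
8756 students aged 12–13) randomized by stratified blocks, with weekly
smoking (at least one cigarette per week) measured two years later. The
question this package addresses is *transportability*: what would the
intervention effect have been in an external target population — here,
12–13-year-olds in serial national school surveys (2004, 2006, 2014, 2016,
2021) — whose covariate mix differs from the trial's and drifts over time
(weekly smoking falling from 3.6% to 0.2%, the ethnic-minority share rising
from 14.4% to 27.8%, residence with a smoker falling from 46.0% to 28.1%)?

Because the underlying microdata are access-restricted, the package ships a
calibrated synthetic-data generator that emulates both sources, so every
stage of the pipeline is testable end to end and parameter recovery can be
checked against known ground truth.

## The estimator

For each survey year the pipeline:

1. **Harmonizes** both sources to one schema (gender; age 12/13 with 11→12
   and 14→13 recodes; ethnicity collapsed to white/minority; smoking status
   never / occasional-experimental-ex / weekly; age at first cigarette;
   residence with a smoker; lesson on smoking) and **stacks** them with a
   selection indicator $S$ (1 = trial, 0 = target), trial rows first.
2. Fits a **selection model** for $P(S=1 \mid X)$ on the stacked data.
3. Computes **inverse odds of selection weights** for trial participants,
   $w_i = (1-p_i)/p_i$; weighted, the trial's covariate distribution
   resembles the target's.
4. Fits a **weighted school random-intercept logistic model** of weekly
   smoking on study arm, adjusted for the six school-level randomization
   stratification variables, by weighted pseudo-likelihood; reports the
   odds ratio with a Wald 95% interval on the log scale.
5. Summarises precision by the **confidence interval ratio**
   $\mathrm{CIR} = \mathrm{upper}/\mathrm{lower}$, a scale-free measure
   that grows as the trial and target drift apart.

Identification rests on conditional population exchangeability (all effect
modifiers that differ between populations are measured — untestable) and
positivity (every target covariate profile occurs in both trial arms —
checked mechanically by `positivity_report()`).

## Design choices that were genuinely open

**Selection-model clustering.** The analysis plan calls for a multilevel
(students-within-schools) selection model. With disjoint trial and survey
school sets, however, $S$ is constant within every school, so a school
random intercept is not identified separately from selection itself: its
estimated SD diverges (empirically ≈27 on the logit scale) and the
covariate-specific selection odds — the only thing the weights need — are
destroyed. `fit_selection_model(random_intercept = "auto")` therefore drops
the school term exactly when $S$ is school-constant (with a message) and
keeps it whenever selection varies within clusters; `"always"` forces the
literal multilevel fit for comparison. School-level dependence re-enters
where it matters, in the outcome model and its variance.

**Prediction scale.** Selection probabilities are computed marginally
(random effects, when present, integrated out by Gauss–Hermite quadrature),
because target schools carry no estimated trial random effect; conditional
prediction is available as a sensitivity option.

**Weighted GLMM and its variance.** A weighted integrated-likelihood GLMM
is not uniquely defined, so the weighted fit uses pseudo-likelihood (the
prior-weights path of `lme4::glmer`) with weights rescaled internally to
mean one — making point estimates exactly invariant to weight scale — and a
school-level cluster-robust sandwich variance. Per-cluster scores of the
integrated weighted likelihood are computed by adaptive Gauss–Hermite
quadrature centred at each school's posterior mode; the model-based
covariance is the bread. The sandwich is conservative with respect to
estimation noise in the weights. With unit weights the point estimate
reduces exactly to the unweighted GLMM; with integer weights (and rescaling
off) it reproduces a row-replicated fit — both are asserted in tests.

**Positivity, by direction.** A covariate level seen only in the *target*
violates population positivity and is an error. A level seen only in the
*trial* (e.g. age-first-smoked 13, absent from two survey waves) has true
inverse selection odds of zero: those trial records are excluded from the
weighted analysis with a warning and a count, rather than letting a
separated coefficient push their weights to zero silently.

**Stratification adjustment.** The six stratification variables enter the
outcome model as fixed-effect indicators. A variable whose level is carried
by fewer than two schools, shows no outcome variation, or is school-level
collinear with the variables already included (screened by QR on the
school-level design) is dropped with a warning — with 59 schools the full
set is kept; the guard matters in small simulations.

**Missing data.** The MAR diagnostic regresses a missingness indicator on
the observed covariates with a school random intercept. Imputation defaults
to chained equations with categorical-appropriate conditionals (logistic or
multinomial, parameters drawn from their approximate posterior, 10 cycles),
since every harmonized variable is categorical; an approximate joint-normal
alternative on indicator codings (bootstrap moment re-estimation per
imputation, conditional draws, probabilistic rounding) mirrors the
multivariate-normal option. Trial and each survey are imputed separately;
weights are re-estimated within each completed dataset and the final
log-ORs pooled by Rubin's rules ($\bar q$, $W$, $B$,
$T = W + (1+1/m)B$) with Barnard–Rubin degrees of freedom and a Monte Carlo
error check (`mcse` $= \sqrt{B/m}$; flagged above 0.1 of the total SE).
With $m = 20$ (the default) the MC error check is comfortably unflagged in
the scenarios tested.

## The synthetic-data generator

The generator's defaults are the published study conditions: trial arm and
school counts, the five survey sample sizes (3958, 3377, 3145, 4874, 3587),
and per-population covariate marginals taken as category counts divided by
their sum (printed percentages are rounded; one printed value, 0.08% for
age-first-13 in the trial, is inconsistent with its count of 71/8756 and
the count is used). Covariates are drawn independently given the
population, with two exceptions:

* a **consistency hook** (on by default) forces never-smokers to report age
  at first cigarette "never", avoiding impossible records. Because every
  population reports slightly *fewer* age-first "never" than status "never",
  the hook makes the two "never" categories coincide and shifts the
  age-first marginal by up to 0.4 percentage points — the price of logical
  consistency; it also makes one selection-model indicator aliased, which
  is detected and dropped.
* optional **school-level covariate clustering** perturbs category
  log-probabilities per school (`covariate_sd`); it is off by default so
  configured marginals are exact.

The follow-up outcome comes from a school random-intercept logistic model
whose intercept is solved numerically (exact enumeration over the covariate
joint × arm, Gauss–Hermite over the random intercept, root-finding to
1e-10) so the marginal prevalence equals the 4.1% target at the configured
arm split and effect. Default effect $\beta_A = \log 0.85$; covariate
effects place most of the signal on baseline smoking status (log-OR 3.0 for
baseline weekly smokers, 1.6 for occasional/experimental/ex), with smaller
terms for residence with a smoker (0.5), age 13 (0.3), gender (0.2) and
ethnicity (−0.3); school SD 0.3 — values chosen once as epidemiologically
plausible for adolescent smoking incidence. Survey school counts are not
published per wave; roughly 35 students per sampled school is assumed. One
master seed expands into per-stage substreams, so adding a stage never
perturbs earlier draws, and equal seeds give byte-identical datasets.

The trial column of the published characteristics table is treated as the
*baseline* covariate distribution, while the follow-up outcome is
calibrated to the abstract's 4.1% follow-up prevalence (both printed values
are 4.1).

What the generator does **not** emulate: covariate dependence beyond the
consistency hook, survey design weights and school-level response-rate
drift, measurement error, or the intervention's peer-diffusion mechanics.
Passing recovery tests therefore show the *estimator* is sound under the
stated data-generating model, not that the published estimates would
reproduce on the restricted microdata.

## Numerical choices

Gauss–Hermite integration uses 25 nodes (15 for per-cluster sandwich
scores, adaptively centred); the calibration root-finder brackets the
intercept generously and fails loudly if no root exists. GLMM fits use
`nAGQ = 1` by default (`nAGQ = 0` is exposed for large replicate
simulations). Effect fits refuse to return estimates whose standard error
exceeds 50 on the log scale (a degenerate fit), and an outcome constant
within an arm is an explicit error. Wald intervals use 1.96 on the log-OR
scale, or a $t$ quantile with Barnard–Rubin df after pooling.

## Problem sizes used in the checks

Parameter-recovery checks run at 50 000 stacked records (200 + 200
schools), where the transported log-OR recovers $\log 0.85$ well within
three standard errors under the first survey wave's covariate shift. The
precision-ordering check runs 100 replicates of three target populations
interpolated between the trial's and the 2021 survey's marginals
(1200 + 1200 records, 20 + 20 schools, `nAGQ = 0`), reproducing the
qualitative pattern of a non-decreasing mean CI ratio as shift grows.
Replicate counts and sizes are fixed in the tests; they were chosen to make
Monte Carlo noise small relative to the assertions.

## Known limitations

* The transported estimand of the weighted outcome model adjusting only for
  arm and stratification variables is marginal over the remaining
  covariates; with a rare outcome the odds ratio is nearly collapsible, so
  under a homogeneous conditional effect the recovery target is
  $\beta_A$ to a very good approximation, but at common outcome
  prevalences the distinction would matter.
* Inference treats the weights as fixed; the school-level sandwich is the
  usual conservative contract, not a full two-stage variance.
* The joint-normal imputation option is an indicator-scale approximation,
  not a full data-augmentation MVN sampler; chained equations is the
  recommended default for these categorical data.
* With very strong covariate shift and a rare outcome (the 2021-like
  extreme), the effective sample size collapses and transported intervals
  become extremely wide; the package reports this honestly (large CI
  ratio, low ESS) rather than truncating weights by default.
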