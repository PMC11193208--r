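---
title: "Assessing baseline imbalance across a portfolio of randomized trials"
author: "rctbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing baseline imbalance across a portfolio of randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rctbalance)
```

## The problem

Randomization exists to make the arms of a trial comparable in everything
but the allocated intervention. Within one trial a baseline difference may
be pure chance; across a *portfolio* of trials of the same drug class,
chance has a precise signature. Under intact randomization,

* per-trial baseline differences (drug arm minus control arm) are as
  often positive as negative;
* pooled across trials with inverse-variance weights they centre on zero
  with between-trial heterogeneity I² = 0;
* the two arms' standard deviations differ only by sampling noise, so
  variance-equality tests produce uniformly distributed p-values; and
* the size of a trial's baseline imbalance carries no information about
  the size of its estimated treatment effect.

`rctbalance` turns each expectation into a computable diagnostic for
summary-level trial tables (one CSV row per trial arm, as extracted from
publications), and ships a seeded portfolio simulator with known truth so
that every diagnostic can be calibrated and power-checked without any
external data.

## Data model

A `trial_set` holds one comparison per (`trial_id`, `control`) pair. Seven
baseline characteristics are tracked: mean age (years), mean LDL-c
(mg/dl) and mean BMI (kg/m²), each with an SD, and percentages of males,
diabetics, smokers and hypertensives. Percentages are stored on the 0--100
scale exactly as printed; proportions appear only inside computations.
The number of decimals of every CSV literal is kept as reported-precision
metadata: a "difference" means a difference in the figures *as published*,
so no internal re-rounding is ever applied, and write/read cycles
reproduce the file field-for-field.

A trial with both a placebo and an ezetimibe control arm contributes two
comparisons sharing a base `trial_id`. The placebo scope selects placebo
comparisons, the ezetimibe scope the ezetimibe ones. For the combined
scope the default (`dual_arm_policy = "both_arms"`) keeps *every*
comparison, so a portfolio of 26 placebo-only, 9 ezetimibe-only and 4
dual-control trials yields 30 + 13 = 43 combined comparisons; this matches
how published combined columns in this literature add up. The alternative
policies (`"placebo_arm"`, `"ezetimibe_arm"`) de-duplicate dual-control
trials to one comparison per base trial for analysts who prefer strict
independence across rows; we made the union the default because the
de-duplicated variant discards extracted comparisons, and because the
within-portfolio dependence it introduces (four shared drug arms) is
negligible at this scale.

## Direction diagnostics: the exact sign test

For a characteristic, each comparison is classified by the sign of its
difference at reported precision; ties and missing fields are excluded.
With `n` informative trials and `k` of them in the majority direction,
the one-sided p-value is the exact binomial tail

$$p = \sum_{j=k}^{n} \binom{n}{j} 2^{-n},$$

computed from the binomial distribution function, not a normal
approximation — portfolios are small (tens of trials) and published
values in this field are exact tails. The test is one-sided *toward the
observed majority*; at a tie, `k = n/2` and `p >= 0.5` follows
automatically. Display rounding is half-up at 3 decimals, the convention
of the tables this mirrors.

One calibration subtlety is worth stating plainly: because the direction
of the test is chosen by the data, the null probability of `p < 0.05` is
not 5% but `2 P(X >= c)` for the smallest `c` whose tail is below 0.05 —
roughly 8% at 40 informative trials, oscillating between 4% and 10% with
`n`. The sign test is therefore a *descriptive* screen whose p-value is
exact for the majority direction actually observed, not a size-α
significance procedure; simulation with the bundled generator makes this
visible directly.

## Pooling baseline differences

Per-trial standard errors are
`sqrt(sd_d^2/n_d + sd_c^2/n_c)` for continuous characteristics and the
binomial `sqrt(p_d(1-p_d)/n_d + p_c(1-p_c)/n_c)` (proportion scale) for
binary ones, using the *reported* percentages — publications rarely give
baseline event counts. This is an approximation at two levels: the
percentages were rounded by the original authors, and estimated-variance
weights are random. The second point has a measurable consequence:
weights are largest exactly when the observed control-arm prevalence
fluctuates toward the boundary, which correlates with a positive risk
difference, so the pooled RD carries a small positive finite-sample bias
of order 1/n (about 0.001 on the proportion scale for a 22% prevalence
and control arms of 50--500). It is clinically negligible but resolvable
by a large simulation; an analyst worried by it can enable the
`continuity` adjustment or supply count-based variances.

Pooling is fixed-effect by construction: under intact randomization every
trial estimates the same quantity (zero), so between-trial heterogeneity
in baseline differences is itself the anomaly being hunted, and a
random-effects model would absorb the signal into its variance component.
We report Cochran's Q, its chi-square p-value, `I² = max(0, (Q - df)/Q)`,
and a test-based 95% CI for I² built on `H = sqrt(Q/(k-1))` (floored at
1) with

* `se(ln H) = (ln Q - ln(k-1)) / (2 (sqrt(2Q) - sqrt(2k-3)))` when
  `Q >= k`, and
* `se(ln H) = sqrt(1/(2(k-2)) (1 - 1/(3(k-2)^2)))` when `Q < k`
  (defined for `k >= 4`; with `Q < k` and `k <= 3` the bounds are
  reported absent),

mapping normal bounds on `ln H` through `I² = 100 (H²-1)/H²` and
truncating to [0, 100]. With a single trial the estimate and CI are the
trial's own and heterogeneity fields are absent — we reserve pooling
language for `k >= 2`. A zero standard error (a 0% or 100% arm) is an
error rather than an infinite weight; the `continuity` option substitutes
`0.5/n` bounds inside the variance only. Confidence intervals use 1.96
throughout; only 95% intervals are reported in this literature.

## SD diagnostics

Systematically larger spreads in the drug arms are a randomization-
integrity signal that survives even when means balance. Three views are
computed:

1. **Directions.** Drug-minus-control SD differences for age, LDL-c and
   BMI feed the same exact sign test.
2. **Pooled SDs.** Per arm, the df-weighted root mean square
   `sqrt(sum((n_i-1) s_i^2) / sum(n_i-1))` over the comparisons that
   report both arms (so the two pools cover the same trials), compared by
   a t-test on the two SD collections. The default is Welch's unpaired
   test, reading the collections as two groups; since arms are
   structurally paired within trials, `mode = "paired"` runs the paired
   alternative — both are reported with their mode label because the
   published analyses do not state which was used. Neither mode weights
   by trial size.
3. **Per-trial variance equality.** With only summary data, Levene's test
   is not computable; the implementable surrogate under normality is the
   variance-ratio F test (larger sample variance over smaller, numerator
   df from the larger-variance arm, two-sided p as twice the smaller
   tail). The simulator can retain individual-level data, for which
   `levene_test()` (absolute deviations from arm means, one-way ANOVA
   form) cross-validates the surrogate; on normal data the two track each
   other closely. The p-values are summarized as a decile histogram with
   the count below 0.05 — under the null they are exactly uniform, which
   the test suite verifies by Kolmogorov–Smirnov on 2000 simulated
   trials.

## Meta-regression of imbalances on outcomes

Per-trial outcome effects are log odds ratios for binary outcomes (MACE,
SAE, any AE, all-cause mortality) and the drug-minus-control difference
in LDL-c change (mg/dl) for the lipid endpoint, with variances
`sum(1/cell)` and `sd_d^2/n_d + sd_c^2/n_c` respectively. When a 2×2 cell
is zero, 0.5 is added to all four cells and the trial is flagged
`corrected`; trials with no events (or all events) in both arms carry no
OR information and are excluded with a logged reason. LDL-c changes
reported as percentages convert through the baseline mean
(`percent_to_absolute_change()`); mg/dl units are used throughout.

Each characteristic × outcome pair gets a univariate random-effects
meta-regression with the method-of-moments (DerSimonian–Laird)
between-trial variance: with fixed weights `W = diag(1/v_i)` and design
`X = (1, x)`,

$$\tau^2 = \max\!\left(0,\;
  \frac{Q_E - (k-2)}{\mathrm{tr}(W) -
  \mathrm{tr}\!\left((X'WX)^{-1} X'W^2X\right)}\right),$$

followed by weighted least squares with weights `1/(v_i + tau^2)`. The
default CI is normal-based; the Knapp–Hartung adjustment (t quantile,
`k - 2` df, residual-scaled variance) is one switch away, since the
published analyses do not name their estimator. Slopes stay on the
log-OR scale per unit of imbalance — `exp(beta)` is annotated alongside,
but we do not restate a slope of −0.56 as "56% lower risk", which is only
exact in the small-beta limit. SAE regressions drop clinical-outcomes
trials by default (their SAE reporting is not comparable with the
lipid-lowering trials), and a sensitivity switch removes those trials
from every regression. No multiple-testing correction is applied; the
number of fitted regressions is recorded in the report metadata.

At least 3 trials and a non-constant moderator are required per fit;
pairs failing that keep a row with an explanatory note so the grid shape
is stable.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the study conditions this package is
aimed at: 43 two-arm trials, 2:1 drug:control allocation (drug arms in
this literature are frequently twice the control size), control arms of
50--500 participants, a hyperlipidaemic population (age 60 (10) years,
LDL-c 120 (35) mg/dl, BMI 29 (5) kg/m², 60% male, 35% diabetic, 22%
smokers, 55% hypertensive), publication rounding to one decimal, and
per-characteristic trial-level missingness at the reporting rates seen in
such portfolios (BMI absent in ~28% of trials, diabetes ~14%, smoking
~42%, hypertension ~37%; age, sex and LDL-c always reported). Continuous
covariates are normal and binary ones Bernoulli — the minimal structure
the portfolio statistics assume; an optional Gaussian copula correlates
BMI and diabetes, off by default. Randomization is broken on purpose via
`imbalance_shift` (additive drug-arm shift) and `sd_inflation`
(multiplicative drug-arm SD factor). Outcomes come from per-participant
logistic models with covariate links and a treatment log OR, so
imbalance–outcome associations of known size can be planted and
recovered end-to-end.

Summaries are computed from individuals, then rounded, then subjected to
missingness, so rounding-induced ties in direction classification arise
exactly as they do in print. A single root seed drives per-trial derived
streams, making portfolios reproducible and trial-level generation order
independent.

What the generator does *not* emulate: correlated covariates beyond the
single copula option, non-normal covariate distributions, informative
(outcome-dependent) missingness, dropout between randomization and
analysis, survival-time outcomes, and publication or reporting bias at
the portfolio level. Passing calibration tests therefore shows the
statistics behave correctly under the stated sampling model, not that
real extraction artefacts (transcription errors, shifting denominators,
post-hoc group merging) are detectable.

## Numerical and design choices

* Exact binomial tails via `pbinom`; verified in the test suite against
  brute-force enumeration of all `2^n` direction vectors for `n <= 20`
  and against exact integer-binomial arithmetic to 1e-12.
* Half-up display rounding (3 decimals for p-values, 2 for estimates) is
  applied only at render time; CSV/JSON outputs carry full precision.
* Degenerate inputs are errors with named trials (zero SE weights, zero
  SDs, arms below 2 participants), except where the published method
  defines a convention (tie handling in the sign test, `k = 1` pools,
  0.5-cell correction, uninformative-trial exclusion).
* Tied SDs give F = 1 with the two-sided p doubling the smaller tail, so
  the test is symmetric under arm exchange even with unequal df.
* Fixed-effect pooling, the I² interval, the DL meta-regression and the
  variance-ratio test are implemented in the package and cross-checked in
  the tests against independent implementations (`metafor::rma` with
  `method = "FE"` / `"DL"`, `car::leveneTest`, `stats::var.test`) — the
  cross-checks are oracles, never the computation path.

## Problem sizes used by the automated checks

The calibration suite simulates 1000 null portfolios of 40 trials for
sign-test and I² calibration, 500 replicates for the −0.16 kg/m² BMI
shift coverage check and for 0.02-slope meta-regression recovery, 2000
trials for variance-ratio uniformity, and 100 replicates of 40 trials at
10% SD inflation for the power check; `scripts/acceptance.R` reruns a
proportionally scaled-down version of the same battery. These sizes give
Monte-Carlo standard errors a few times smaller than the tolerance bands
they are checked against.

## Known limitations

* RD pooling weights come from reported percentages, with the
  finite-sample bias discussed above; count-based variances are the
  remedy when counts are available.
* The directional sign test is descriptive (see its section); its
  rejection rate under the null is about 2α by construction.
* SD reconstruction from standard errors or CIs is the data preparer's
  job; the package consumes SDs as given.
* Multivariate meta-regression (mutually adjusted imbalances) is out of
  scope at portfolio sizes of ~40 trials.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_trials = 43,
                  control = c(rep("placebo", 30), rep("ezetimibe", 13)),
                  imbalance_shift = c(bmi = -0.16), seed = 42)
portfolio <- simulate_outcomes(simulate_portfolio(cfg,
                                                  keep_individual = TRUE))
report <- run_assessment(portfolio$trial_set)
report$tables$pooled[report$tables$pooled$characteristic == "bmi", ]
render_report(report, "assessment-out", fig = TRUE)
```
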