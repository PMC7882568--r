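---
title: "Parallel multiple mediation for gambling survey data: models, design choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel multiple mediation for gambling survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Population surveys routinely find that players of particular game types
(electronic gaming machines, poker, live betting, ...) report more
gambling problems. Regression adjustment for demographics and overall
involvement shrinks those associations, but it answers only *whether*
an association survives adjustment, not *through which mechanism* a
game type is linked to problems. This package takes the mediation view:
for each focal game type, last-year participation `X` (0/1) is related
to a problem-gambling score `Y` (Problem Gambling Severity Index, PGSI,
nine items scored 0-3, sum 0-27) through six parallel mediators,

* `M1` demographic problem-gambling propensity (a fitted probability,
  see below),
* `M2` breadth of involvement: number of game types played in the last
  year, capped at 7,
* `M3` frequency of play within the focal type (ordinal categories
  0 = never ... 5 = daily, treated as metric),
* `M4` maximum frequency across the 14 other types,
* `M5` usual spending per session within the focal type (winsorized
  currency),
* `M6` maximum winsorized usual spending across the other types.

Estimation is ordinary-least-squares path analysis. Each a-path is the
simple regression slope of a mediator on `X`; the b-paths and the
direct effect `c'` come from one joint regression of `Y` on `X` and all
six mediators. The indirect effect through mediator *j* is the product
`a_j b_j`; the total effect is `c' + sum_j a_j b_j`, which for OLS with
intercepts equals the simple regression slope of `Y` on `X` exactly.
The engine verifies this identity on every fit *and inside every
bootstrap resample* and records the largest discrepancy
(`fit$decomp_max_err`); anything above 1e-10 would indicate a numerical
defect.

Inference uses the nonparametric percentile bootstrap: rows are
resampled with replacement `B` times (default 5000), all paths
re-estimated per resample, and each effect's interval is the empirical
`(alpha/2, 1-alpha/2)` quantile interval of its bootstrap distribution.
An effect is called *relevant* when its interval excludes zero. The
percentile bootstrap is preferred over normal-theory product tests
because the mediators are strongly intercorrelated and the product
`a_j b_j` is not normal in finite samples. No multiplicity adjustment
is applied by default, matching the exploratory character of the
analysis; `p.adjust`-style correction can be layered on by the user.

```{r}
library(gcmm)
sim <- simulate_survey(gcmm_sim_params(rng_seed = 1))
gamblers <- filter_last_year_gamblers(sim$table)
fit <- gcmm(gamblers, "egm_off", B = 5000, seed = 1)
summary(fit)
plot(fit)
```

## Feature engineering, in order

Given a survey table restricted to last-year gamblers (at least one
frequency category >= 1), `build_featureset()` executes:

1. **Missing depth responses to zero.** Among last-year gamblers a
   missing frequency or spending answer is read as "did not play /
   spent nothing" for that type.
2. **Spending winsorization**, per type, pooled over survey years:
   values outside the 1st-99th interpolated percentiles are replaced by
   the percentile values. The order matters: the imputed zeros are part
   of the sample over which percentiles are computed. Frequency is not
   winsorized (six bounded categories carry little outlier risk).
3. **Participation and breadth.** `X = 1` iff frequency >= 1; breadth
   is the row count of played types, capped at 7. The caps (breadth 7,
   PGSI 6) default to fixed published values for reproducibility; a
   `percentile99` mode re-derives them for new data sets.
4. **Beyond-type aggregates** by the maximum over the 14 non-focal
   types (frequency, and winsorized spending). The maximum, rather than
   the sum, is used precisely to avoid near-collinearity with breadth.
5. **Demographic propensity.** A binary logistic regression predicts
   PGSI >= 5 (at least moderate risk) from male gender, education
   (three ordered levels entered as one metric term), being
   single/divorced/widowed, and age in years. The fitted probability is
   the propensity score; respondents with missing demographics receive
   the mean score of scored respondents. The probability scale makes
   this mediator a formative index comparable in spirit to the
   behavioural mediators; education enters as a single metric term so
   one odds ratio summarises the gradient.
6. **Outcome capping.** PGSI scores above 6 are set to 6.

Two open choices were settled as follows. Percentiles (winsorization,
caps, bootstrap intervals) use one quantile definition package-wide:
linear interpolation between closest ranks (`stats::quantile` type 7).
A consequence worth knowing: winsorization under an interpolated
percentile is exactly idempotent only when the percentile lands on an
integer rank; otherwise a second pass can move values already clamped
to the cut by a tail-local amount. And the propensity score is stored
as a probability; the linear predictor differs only by a monotone
transform and did not change any downstream conclusion in simulation.

## Cohort comparisons

Before pooling several survey waves into one analysis sample, the
package quantifies cohort differences: participation-by-year 2xk
contingency tables with the asymptotic chi-square statistic (no
continuity correction) and Cramér's V = sqrt(chi2 / (N min(r-1, c-1)));
Kruskal-Wallis tests (tie-corrected H) with the effect size
eta^2 = (H - k + 1)/(n - k) for metric and ordinal constructs; and
last/first participation-rate growth ratios with unweighted means per
offline/online group. Expected cells below 5 raise a sparseness flag
and an optional Monte-Carlo exact p-value; the reported statistics stay
chi-square throughout. The judgement of whether small effect sizes
justify pooling stays with the analyst — the package reports, it does
not decide.

## The dominant-mediator profile rule

For each game type the relevant (interval excluding zero) and positive
(problem-increasing) indirect effects are ranked by their unrounded
point estimates. The largest identifies the dominant mediator; the
dominance ratio is largest / second-largest. Profiles are labelled by
the dominant mediator (`breadth_dominant`,
`frequency_within_dominant`, `other_dominant`), or `equivocal` when the
ratio falls below the threshold, or `none_relevant` with no candidate.
The default threshold 2 sits between published distinct profiles
(ratios 2.20-3.96) and the one equivocal case (1.64); it is
configurable, and ties break on the fixed mediator order M1-M6.
Negative indirect effects never enter the ranking regardless of
magnitude: a problem-*decreasing* pathway cannot be the dominant
problem-increasing mechanism. No inferential test is attached to the
ratio itself — it is a descriptive rule.

`fit_from_effects()` assembles a minimal fit object from externally
reported indirect effects and interval bounds, so the rule can be
applied to published effect tables without refitting.

## The synthetic survey generator

Real respondent-level gambling surveys are rarely deposited, so the
package ships a generator whose output has the structure the pipeline
assumes, with known ground truth:

* **Involvement.** One latent standard-normal involvement factor per
  respondent; each type's participation latent loads on it with weight
  sqrt(rho) (default rho = 0.3), thresholded at the type's marginal
  participation probability (defaults span 1.4% to 73.7%, the observed
  per-type range). This induces the positive cross-type participation
  correlation that breadth relies on, with a single knob.
* **Frequency.** Conditional on participation, the latent exceedance
  maps monotonically into categories 1-5 with configurable
  probabilities (default 0.55/0.25/0.12/0.05/0.03) — more involved
  respondents land in higher categories.
* **Spending.** Lognormal per-session spending (default median 1000
  currency units, log-sd 1) whose log shares the type latent with
  loading 0.4 (the within-type frequency-spending correlation is not
  known from published sources; it is exposed as a parameter rather
  than asserted), plus a rare inflated tail (1% of values scaled 10x)
  so that winsorization visibly matters.
* **Demographics.** Gender, age (truncated normal 18-70, mean 42.57,
  sd 14.39), three education levels, partnership — marginals matching
  the pooled survey sample.
* **Outcome.** Two modes. In the realistic `"mixture"` mode a logistic
  model in the demographics, with odds ratios male 5.026, education
  0.527, single 1.671, age 0.951 per year, drives a rare high-risk
  indicator; the intercept is calibrated at generation time so the
  moderate-risk-plus rate among last-year gamblers hits a target
  (default 1.2%). High-risk respondents draw PGSI >= 5; everyone else
  draws a zero-inflated 0-4 score from the behaviour constructs. In the
  `"linear"` validation mode, PGSI is the rounded linear predictor over
  the *post-feature-engineering* mediator constructs plus Gaussian
  noise.
* **Missingness.** Cell-level rates for the frequency and spending
  blocks and a row-level rate for demographics (default 2.94%, the
  published propensity-score missingness), injected before the outcome
  is assigned so planted paths are defined on exactly the imputed
  constructs the analysis will see.
* **Ground truth.** At generation time the realized a-paths (simple
  OLS slopes of each construct on participation, from the same draws)
  are recorded together with the planted b coefficients and their
  products, enabling exact recovery tests: the analysis reproduces the
  recorded a-paths to machine precision on the same sample.

What the generator does **not** emulate: the joint Icelandic
distribution beyond these marginal and threshold targets, survey
weighting (the source analyses were unweighted), item-level PGSI
response behaviour, and any real measurement error or recall bias.
Passing tests on generated data therefore validate the *procedure* —
estimation, inference, classification — not substantive conclusions
about any real population.

## Validation scenarios and their design

Four preset scenarios (see `?scenarios`) fix the simulation designs
used by the test suite; their problem sizes are chosen so each check
has adequate power while a full validation run stays comfortable on a
single CPU.

**Path recovery** (`sim_params_recovery()`): linear outcome mode with
planted coefficients (breadth 0.35, frequency-within 0.45,
frequency-beyond 0.25, spending 2e-4/1e-4 per currency unit,
propensity 0), intercept 8 and noise sd 2 so the integer PGSI scale
truncates essentially nothing, about 5000 last-year gamblers per
replicate, 100 replicates. Because coefficient recovery is defined on
the untransformed linear outcome, the companion `recovery_config()`
leaves the PGSI cap at 27; the default cap 6 would deliberately
truncate the planted truth. Each indirect-effect estimate's mean is
required to sit within 3 Monte-Carlo standard errors of the recorded
truth.

**Bootstrap calibration** (`sim_params_calibration()`): the same
design at about 1000 gamblers with the frequency-beyond coefficient
set to zero — a mediator with a nonzero a-path, a null b-path, and a
well-spread ordinal regressor, so its indirect effect is exactly null
and its test statistic is regular. Over 500 replicates with B = 1000
the 95% interval must exclude zero at 5% plus or minus 2 percentage
points. The *sparse* spending-within mediator is deliberately not used
as the null probe: it is a point mass at zero for all non-participants
(roughly 88% of the sample at the focal type's participation rate), so
its b-path rests on a few hundred heavy-tailed observations and its
percentile interval is genuinely anti-conservative there (about 9-10%
measured) — a known limitation of percentile intervals under sparse
skewed regressors, which applies equally to real spending mediators
and is worth remembering when reading spending rows in output tables.

**Profile recovery** (`sim_params_profile_plant()`): ten types planted
breadth-dominant and five frequency-within-dominant (the five types
found frequency-driven in the source analysis), about 4500
respondents. Two design devices keep the plant clean. First, the five
frequency effects are *participation-centred*, beta (freq - c X) with
c the mean conditional category: the within-type b-path is still
exactly beta (the -beta c X part folds into the direct effect, giving
the planted types a negative direct component, as observed empirically
for machine and poker play), but the effect no longer loads on the
breadth count through the participation indicator. Second, rho = 0 in
this scenario: with a shared involvement factor, *every* intensity
regressor proxies the omitted planted effects of the other types,
which blurs the profile boundary — an instructive observation in
itself: under strong cross-game dependence the attribution of
dominance between breadth and within-type intensity is intrinsically
harder. Coefficients (breadth 1.1, frequency 2.2 centred) realise a
true dominance ratio of at least 3 for every type in every replicate.
The (10, 5) split must be recovered in at least 95% of 50 replicates
(B = 300 per fit for the relevance flags).

**Propensity recovery** (`sim_params_propensity()`): mixture mode,
n = 60,000 (about 50,000 gamblers), with the high-risk rate raised to
10%: at the realistic 1.2% rate a sample of this size yields only
about 600 outcome events and the male odds-ratio's standard error
(about 0.12 on the log scale) would exceed the 10% recovery band —
the scenario is powered to test the estimator, not the rarity. All
four odds ratios must be recovered within 10%.

## Numerical choices and degenerate inputs

* One quantile rule everywhere: type 7 interpolation.
* Bootstrap resamples whose outcome design is rank deficient are
  redrawn, not dropped, keeping exactly B draws (percentile ranks
  assume fixed B); the redraw count is reported, and more than 10%
  deficient resamples aborts with a diagnostic.
* Seeds: all randomness is governed by explicit seeds; per-type fits
  inside `gcmm_all()` use seeds derived from the master seed, and both
  the generator and the bootstrap restore the caller's RNG state.
* Constant participation (a type played by everyone or no one) and
  constant mediators are refused with the offending column named;
  single-class propensity outcomes and non-convergent logistic fits
  are errors, not silent fallbacks.
* A constant outcome yields zero slopes and degenerate zero-width
  intervals for all slope-derived effects, not an error.

## Limitations

The mediation model is linear and additive in constructs that are
skewed even after winsorization; OLS point estimates are consistent
under the model but real spending data will stress the linearity
assumption. Percentile intervals for indirect effects through sparse,
heavy-tailed mediators (spending within a rarely played type) can be
anti-conservative, as quantified above. Cross-sectional mediation
supports mechanism *decomposition*, not causal ordering. Serial or
moderated mediation, correlated-mediator SEM, and nominal multi-class
outcome models are out of scope.
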