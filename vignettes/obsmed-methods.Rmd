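---
title: "Methods: oxidative balance, survey-weighted regression, and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxidative balance, survey-weighted regression, and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`obsmed` implements the analysis chain used to ask whether serum
methylmalonic acid (MMA) mediates the association between the oxidative
balance score (OBS) and cardiovascular disease (CVD) in a hypertensive
complex-survey cohort. This vignette is the package's own account of the
statistical machinery: the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one
reasonable choice existed.

## The oxidative balance score

The OBS summarizes pro- versus antioxidant exposure over 20 components:
16 dietary intakes from 24-hour recall and 4 lifestyle factors (physical
activity as a MET score, tobacco exposure as serum cotinine, alcohol
consumption in g/day, and BMI). Five components are pro-oxidants (total
fat, total iron intake, cotinine, alcohol, BMI); the other 15 are
antioxidants. Every component except alcohol is scored by
gender-specific tertiles: antioxidants earn 0/1/2 points from the lowest
to the highest tertile and pro-oxidants 2/1/0, so the total lies in
[0, 40] with higher totals meaning greater antioxidant exposure.
Alcohol is scored categorically: nondrinkers (exactly 0 g/day) earn 2
points, moderate drinkers 1, and heavy drinkers 0, with the heavy
threshold at 15 g/day for women and 30 g/day for men; intake exactly at
the threshold is heavy.

Several details are not pinned down by the score's verbal definition and
are resolved here explicitly:

* **Tertile estimator.** Cutoffs are unweighted type-1 (inverse-ECDF)
  empirical quantiles at 1/3 and 2/3 within gender. The type-1 choice
  makes the cutoffs observed values, so nine values 1..9 cut at (3, 6)
  into thirds of equal size.
* **Tie rule.** A value exactly equal to a cutoff falls in the *lower*
  tertile. This is deterministic and keeps tertile membership a pure
  function of the data.
* **Dietary component set.** The 14 antioxidant intakes (fiber,
  carotene, riboflavin, niacin, vitamin B6, total folate, vitamin B12,
  vitamin C, vitamin E, calcium, magnesium, zinc, copper, selenium) and
  2 pro-oxidant intakes (total fat, iron) follow the commonly used
  NHANES OBS scheme. The registry (`obs_registry()`, or a YAML file) is
  the source of truth and is validated against the 16 + 4 and 5 + 15
  count invariants, so alternative component sets can be swapped in.
* **BMI** is scored by gender-specific tertiles like the other
  continuous components, not by fixed clinical categories.
* **Exposure dichotomy.** The exposure contrast is the first score
  tertile against the rest: `low` iff `total < cutoff`, with the cutoff
  recomputed as the 1/3 quantile of totals in the analytic sample by
  default (a fixed numeric cutoff can be supplied instead). A total
  exactly at the cutoff is `high`.

Participants missing any component receive no score and are excluded,
mirroring the usual analytic-sample construction.

## Survey-weighted logistic regression

All association models are logistic regressions fitted by maximizing the
weighted pseudo-likelihood, with variance estimated by Taylor-series
linearization over (stratum, PSU) clusters under the with-replacement
PSU approximation — the estimator recommended for public-release
NHANES-style designs. Weights are sampling weights: rescaling them all
by a constant changes nothing. With equal weights and no clustering the
point estimates equal the ordinary MLE and the linearized variance
reduces to the familiar clustered sandwich with singleton clusters.

Choices worth knowing about:

* **Single-PSU strata** make the design-based variance undefined; the
  fit errors by default and can instead center lonely PSUs at the grand
  mean (`single_psu = "center"`), which is conservative.
* **P-values** use the large-sample normal reference by default;
  `summary(fit, df = "design")` switches to a t reference with
  #PSUs − #strata degrees of freedom.
* **Missing data** are handled complete-case within each fit unless the
  multiple-imputation pathway is engaged.
* **Separation** and non-convergence are flagged on the returned object
  and produce warnings; odds ratios from flagged fits warn again rather
  than failing silently.

Weighted descriptive statistics use the Hajek mean with linearized SE,
and categorical associations use the first-order Rao-Scott corrected
chi-square: the weighted Pearson statistic divided by the mean
generalized design effect, estimated as `tr(Vsrs^-1 Vdesign)/df` with
both covariances of the free-cell residuals computed under the same
with-replacement scaling. Computing the correction as this ratio makes
the equal-weight, unclustered case collapse *exactly* to the classical
Pearson statistic. When the residual variance degenerates (e.g. perfect
association) the correction is skipped and the uncorrected statistic
stands.

## Restricted cubic splines and the mediator cutoff

The dose-response of CVD on continuous MMA is modelled with a restricted
cubic spline in the truncated-power parameterization: `k` knots give
`k − 1` basis columns (linear term plus `k − 2` cubic terms), and any
fitted curve is linear beyond the boundary knots. The default is 4 knots
at the 5th/35th/65th/95th percentiles, standard practice when the knot
count is otherwise unspecified; 3 or 5 knots and explicit knot vectors
are supported. Both the overall association (all spline terms) and
nonlinearity (cubic terms only) are tested with design-consistent Wald
statistics — Wald rather than likelihood-ratio because design-based fits
maximize a pseudo-likelihood, for which LR statistics lose their usual
reference distribution.

The *inflection point* — the predictor value where the fitted log-odds
curve changes direction — is located by evaluating the curve on a
uniform 512-point grid between the boundary knots and finding the first
sign change of the numerical derivative; derivative magnitudes below
1e-8 are treated as plateaus, not crossings, and multiple crossings are
all recorded with the first returned. The mediator's dichotomization
cutoff then follows the "nearest interpretable value" policy: the sample
median is used when it lies within 10% of the IQR from the inflection
(the situation where the inflection effectively *is* the median), else
the inflection itself is used with a note. The 10%-of-IQR tolerance
reproduces the logic of preferring a quantile-anchored cutoff without
hard-coding any particular published value; `inflection_exact` is
available when the raw turning point is wanted.

## Mediation by the distribution-of-product method

With binary exposure (low vs high OBS), binary mediator (high vs low
MMA) and binary outcome, three weighted logistic fits on the same
analytic rows give, on the log-OR scale, the total effect *c*
(`outcome ~ exposure + covariates`), path *a*
(`mediator ~ exposure + covariates`), and paths *b* and *c′*
(`outcome ~ exposure + mediator + covariates`). The indirect effect is
the product *ab*; its confidence interval is taken from the
distribution of `Z1 * Z2` with `Z1 ~ N(a, se_a^2)`,
`Z2 ~ N(b, se_b^2)` independent, computed by seeded Monte Carlo with
10^6 draws by default. Monte Carlo was chosen over Meeker-style
numerical integration because it is trivially oracle-checkable at desk
scale and reproducible given the seed; the analytic Sobel interval is
always attached for comparison, and the two agree closely when both
paths are several standard errors from zero. Mediation is declared when
the interval excludes 0 — equivalently, when the indirect OR interval
`exp(ab_ci)` excludes 1.

The **mediated proportion** is `ab / c`, indirect over total on the
log-OR scale. The alternative `ab / (ab + c′)` was rejected because the
published worked example this package uses as its acceptance surface
(product estimate 0.071 against a total-effect OR of 1.61, reported as
14.9%) is consistent only with `ab / c`. When `ab` and `c` disagree in
sign the ratio is flagged as inconsistent (suppression) rather than
presented as a proportion.

Assumptions and caveats, stated rather than hidden:

* *a* and *b* are treated as independent across the two fits, the
  standard product-of-coefficients assumption.
* Combining log-ORs across models is exact only for rare outcomes
  (logistic non-collapsibility). The decomposition gap
  `|c − (c′ + ab)|` is computed and reported with every mediation
  record, never suppressed.
* Subgroup analyses (e.g. by diabetes or dyslipidemia) refit all three
  models within the stratum, dropping the stratifying variable from the
  covariate set; the OBS and MMA cutoffs are *not* recomputed per
  subgroup, matching the single-cutoff convention of the analysis this
  package operationalizes. Degenerate strata are skipped with a logged
  message.

## Multiple imputation and pooling

Education, WBC and serum vitamin B12 are imputable via chained
univariate regressions: normal-theory linear regression with posterior
parameter draws and stochastic residual draws for continuous columns,
multinomial logistic regression with category draws for education, 10
cycles per completed dataset. The multinomial step draws categories from
the fitted probabilities without a parameter draw — a mild approximation
noted here. Observed cells are never modified, and with zero
missingness the pathway returns exact copies, so the MI and
complete-case pipelines coincide on complete data. Fits across the `m`
datasets are combined by Rubin's rules (mean coefficients; within +
`(1 + 1/m)` between covariance; the classical per-term degrees of
freedom). MCAR is the only missingness mechanism the generator produces,
which keeps the MI validity simulations interpretable: under MCAR the
complete-data fit is the estimand the pooled fit must recover.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws NHANES-like hypertensive cohorts with a known
mediation structure so every stage is testable without external data.
It emulates:

* a two-stage design — `n_strata` strata (default 14) by
  `psu_per_stratum` PSUs (default 2, the minimum for design-based
  variance), with uniform weights on `weight_range` drawn independently
  of everything else, so weighted and unweighted estimands coincide in
  truth and recovery tests are well-defined;
* gender-specific, right-skewed (log-normal) component distributions
  with typical adult intake medians and a −0.2 log-scale shift for
  women;
* a latent low-OBS exposure defined as the first tertile of the OBS
  computed on the generated components themselves, so the analytic
  dichotomy and the generative truth agree by construction;
* an OBS→MMA path: the latent high-MMA state is Bernoulli with log-odds
  shifted by `alpha_m` (default log 1.32) for low-OBS participants,
  calibrated so the marginal rate is 1/2; MMA values are then drawn from
  the matching half of a log-normal centered at 154.9 nmol/L. The
  half-draw construction (rather than a pure location shift) makes the
  injected `alpha_m` *exact* on the median split, which is what a
  parameter-recovery test needs — a location shift would inject the
  coefficient only approximately and bias recovery at large n;
* direct (`gamma_direct`, default log 1.50) and mediator (`beta_m`,
  default log 1.34) effects on CVD plus configurable covariate effects,
  with the intercept calibrated by root-finding to a target prevalence
  (default 0.20, the study-scale CVD rate);
* a U-shaped contribution of log-MMA to the CVD log-odds
  (`mma_curvature`, default 0.6) with its minimum at the MMA median.
  This gives the spline stage a genuine direction change to detect. The
  term depends on MMA only through `(log MMA − log 154.9)^2`, which is
  independent of the high/low state and of every fitted regressor, so it
  perturbs the injected path coefficients only through logistic
  marginalization — under 1% at the default magnitude;
* MCAR missingness in education, WBC and vitamin B12.

It deliberately does **not** emulate: informative sampling (weights
correlated with outcomes), 24-hour-recall measurement error, NHANES
questionnaire logic (the MET score is emitted directly, since the
activity-item computation is unspecified at this level), seasonal or
day-of-week intake structure, or missingness mechanisms beyond MCAR.
Passing tests on these cohorts therefore demonstrate the correctness of
the estimators under a clean design, not robustness to the messier
features of real survey data.

One behavior of the full pipeline on synthetic data is worth flagging:
because the mediator's effect enters the truth as a step at the MMA
median, the spline — which smooths the step over the span between two
knots — places its fitted minimum systematically left of the median
(roughly 130–140 nmol/L at the default settings). The cutoff policy then
correctly reports that the inflection does not coincide with the median
and uses the inflection. This is the designed fallback branch, not an
error; real dose-response curves with a smooth turning point at the
median exercise the other branch, as the unit tests do directly.

## Numerical choices

* IRLS with a 1e-10 relative pseudo-deviance tolerance, 30-iteration
  cap; fitted probabilities clamped away from 0/1 by 1e-12; rank
  deficiency detected by QR and reported with the aliased column names.
* Weights are normalized to mean 1 inside the optimizer (the estimating
  equations are homogeneous in the weights), which improves conditioning
  without changing any estimate.
* The spline basis scales its cubic terms by the squared boundary-knot
  span so all coefficients live on comparable scales.
* Monte Carlo quantiles use the default type-7 definition; intervals are
  reproducible from an integer seed, and seeded helpers restore the
  caller's RNG state.
* Report serialization keeps full double precision in JSON; rounding is
  a presentation concern only.

## Problem sizes used in the checks

The package's validation suites run at sizes chosen to keep Monte Carlo
error well inside the asserted bands: path-recovery uses 200 cohorts of
n = 20,000; distribution-of-product coverage uses 2,000 replicates over
a 9-point (a, b) grid at 5 × 10^4 draws per interval, with the interval
itself oracle-checked against 10^7-draw brute force; nonlinearity
test size uses 500 replicates at n = 600; imputation recovery uses 100
replicates at n = 1,000. The acceptance script reruns scaled versions of
the same computations from a user-supplied seed.

## Known limitations

* Replicate-weight (BRR/Fay) variance estimation is not implemented;
  the with-replacement linearization is the only variance engine.
* Counterfactual (natural effect) mediation, exposure-mediator
  interaction decomposition, and multiple mediators are out of scope;
  the interaction model is provided as a diagnostic for the no-interaction
  assumption.
* The mediated proportion inherits all caveats of ratio-of-log-OR
  summaries for non-rare outcomes; read it together with the reported
  decomposition gap.
* Energy adjustment of dietary intakes (residual method) and multi-day
  recall averaging are not performed.
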