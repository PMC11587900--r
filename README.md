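# obsmed

Does serum methylmalonic acid (MMA) mediate the association between
oxidative balance and cardiovascular disease (CVD)? `obsmed` is an R
package for epidemiologists working with complex-survey cohorts
(NHANES-style designs with weights, strata and PSUs) who want to run
that full analysis chain — and validate every stage of it — without
leaving R:

* **Oxidative balance score (OBS)**: the 20-component score (16 dietary +
  4 lifestyle; 5 pro-oxidants, 15 antioxidants) with gender-specific
  tertile scoring, the categorical alcohol rule, and first-tertile
  dichotomization of the total.
* **Survey-weighted logistic regression** with design-based
  (Taylor-linearized) variance over (stratum, PSU) clusters, odds-ratio
  tables, weighted means/SEs, and Rao-Scott design-adjusted chi-square
  tests.
* **Restricted cubic splines** for the MMA dose-response, with
  design-consistent tests of overall association and nonlinearity and
  grid-based detection of the inflection point used to choose the
  mediator's cutoff.
* **Distribution-of-product mediation**: paths a (OBS→MMA), b
  (MMA→CVD | OBS), c (total) and c′ (direct) from weighted logistic
  fits; a Monte Carlo confidence interval for the product *ab* from the
  distribution of the product of two independent normals; the indirect
  odds ratio `exp(ab)`; and the mediated proportion `ab / c` on the
  log-OR scale — with subgroup analyses and an always-reported
  decomposition diagnostic `|c − (c′ + ab)|`.
* **Multiple imputation** by chained regressions with Rubin pooling for
  the sensitivity pathway.
* **A synthetic cohort generator** with known ground truth
  (configurable path coefficients on the log-odds scale, a two-stage
  design, MCAR missingness) so that parameter recovery, interval
  coverage, and test size are all checkable.

The statistical core in brief: with binary exposure X (low vs high
OBS), binary mediator M (high vs low MMA) and binary outcome Y, three
survey-weighted logistic fits give

```
logit P(Y=1) = c  X + γ'Z              (total effect)
logit P(M=1) = a  X + α'Z              (path a)
logit P(Y=1) = c' X + b M + β'Z        (paths b, c')
```

and the indirect effect ab gets its 95% CI from the quantiles of
Z₁·Z₂, Z₁ ~ N(â, se_a²), Z₂ ~ N(b̂, se_b²) independent; mediation is
declared when that interval excludes 0, and the mediated proportion is
ab/c.

## Worked example

Generate a cohort with known truth (paths a = log 1.32, b = log 1.34,
c′ = log 1.50 by default), score the OBS, dichotomize MMA at its
median, and run the mediation analysis:

```r
library(obsmed)

cohort <- generate_cohort(truth_params(n = 20000, seed = 1))
obs <- compute_obs(cohort)
cohort$obs_group <- dichotomize_obs(obs$obs_total)
cohort$mma_group <- factor(ifelse(cohort$mma >= median(cohort$mma),
                                  "high", "low"),
                           levels = c("low", "high"))
design <- svy_design(cohort, weights = "weight", strata = "stratum",
                     ids = "psu")

fit <- svy_logit(cvd ~ obs_group + age + gender + diabetes + dyslipidemia,
                 design)
odds_ratios(fit)[1, ]
#>           term       or   lower    upper            p
#> 1 obs_grouplow 1.591291 1.47361 1.718371 2.136196e-32

run_mediation("obs_group", "mma_group", "cvd",
              c("age", "gender", "diabetes", "dyslipidemia"),
              design, draws = 1e6, seed = 7)
#> Mediation of obs_group -> mma_group -> cvd (log-OR scale paths)
#>
#>  population     n total_or direct_or dop_beta dop_lower dop_upper indirect_or
#>       total 20000     1.59      1.57   0.0668    0.0372     0.101        1.07
#>  indirect_or_lower indirect_or_upper mediated_pct decomposition_gap
#>               1.04              1.11         14.4             0.051
#>  mediation_present
#>               TRUE
```

Reading the output: low OBS raises the odds of CVD (total OR 1.59);
most of that is direct (OR 1.57), but the indirect route through high
MMA is real — the distribution-of-product interval (0.037, 0.101)
excludes 0, the indirect OR is 1.07, and about 14% of the total log-OR
flows through the mediator. The decomposition gap of 0.051 quantifies
the non-collapsibility slippage in combining log-ORs for a non-rare
outcome. Single-cohort estimates carry sampling noise; the injected
truth is recovered in distribution across replicates (see the test
suite).

The whole chain — exclusions, OBS scoring, spline-based cutoff
selection, descriptive tables, Model I/II odds-ratio tables, mediation
with subgroups, interaction models, and an MI sensitivity rerun — is
orchestrated by `run_full_analysis(pipeline_config(...))` or from a
YAML file (see `inst/extdata/example_config.yaml`), with a thin CLI at
`inst/scripts/obsmed.R`.

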