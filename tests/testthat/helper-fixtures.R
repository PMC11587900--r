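# Shared fixtures: tiny designs and simulated logistic data built in code.

# iid logistic data with an optional second covariate
sim_logistic <- function(n, beta = c(-0.5, 0.8), seed = 1) {
  withr::local_seed(seed)
  x <- stats::rnorm(n)
  eta <- beta[1] + beta[2] * x
  data.frame(x = x, y = stats::rbinom(n, 1L, stats::plogis(eta)))
}

# small clustered design: n_strata strata x 2 PSUs, m obs per PSU
toy_cluster_design <- function(n_strata = 3, m = 8, seed = 1) {
  withr::local_seed(seed)
  st <- rep(seq_len(n_strata), each = 2 * m)
  cl <- rep(seq_len(2 * n_strata), each = m)
  d <- data.frame(
    stratum = st, psu = cl,
    w = stats::runif(n_strata * 2 * m, 0.5, 3),
    x = stats::rnorm(n_strata * 2 * m),
    g = sample(c("a", "b"), n_strata * 2 * m, replace = TRUE),
    y = stats::rbinom(n_strata * 2 * m, 1L, 0.4))
  svy_design(d, weights = "w", strata = "stratum", ids = "psu")
}

# small cohort generated with zero missingness (fast default for tests)
test_cohort <- function(n = 1500, seed = 1, ...) {
  generate_cohort(truth_params(n = n, seed = seed,
                               missing_rates = numeric(), ...))
}

# add analysis groupings used by the path models
add_groups <- function(cohort) {
  cohort$obs_group <- factor(ifelse(cohort$low_obs_true == 1, "low", "high"),
                             levels = c("high", "low"))
  cohort$mma_group <- factor(
    ifelse(cohort$mma >= stats::median(cohort$mma), "high", "low"),
    levels = c("low", "high"))
  cohort
}
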