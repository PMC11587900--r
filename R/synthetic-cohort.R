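#' Ground-truth parameters for synthetic NHANES-like cohorts
#'
#' Defines the generative model for a hypertensive survey cohort with a
#' known mediation structure: a latent low-OBS exposure raises the odds of
#' high methylmalonic acid (path `alpha_m`), high MMA raises the odds of
#' cardiovascular disease given OBS (path `beta_m`), and low OBS has a
#' direct effect on CVD (path `gamma_direct`), all on the log-odds scale.
#' Defaults mirror the magnitudes reported for NHANES 2011-2014
#' hypertensive adults: n = 4137, paths log(1.32)/log(1.34)/log(1.50),
#' CVD prevalence 0.20, and modest MCAR missingness in education, WBC and
#' vitamin B12.
#'
#' @param n participant count.
#' @param n_strata number of sampling strata.
#' @param psu_per_stratum PSUs per stratum (>= 2 whenever design-based
#'   variance will be requested downstream).
#' @param weight_range range of the uniform sampling-weight draw; weights
#'   are independent of all outcomes, so weighted and unweighted estimands
#'   coincide in truth.
#' @param alpha_m log-OR of low OBS on high MMA (path a).
#' @param beta_m log-OR of high MMA on CVD given OBS (path b).
#' @param gamma_direct direct log-OR of low OBS on CVD (path c').
#' @param mma_curvature curvature of the U-shaped contribution of
#'   log-MMA to the CVD log-odds, with minimum at the MMA median
#'   (154.9 nmol/L).  Together with the `beta_m` jump of the latent
#'   high-MMA state this produces a J-shaped dose-response whose slope
#'   changes sign at the median, the feature the spline stage detects.
#'   The term depends on MMA only through `(log MMA - log 154.9)^2`,
#'   which is independent of the high/low MMA state and of all other
#'   regressors, so it perturbs no injected path coefficient.  Set to 0
#'   for a monotone step dose-response.
#' @param covariate_effects named numeric vector of log-ORs on CVD for
#'   cohort columns (numeric columns enter centered).
#' @param baseline_prevalence target marginal CVD prevalence in (0, 1).
#' @param missing_rates named vector of MCAR missingness fractions in
#'   `[0, 1)` applied after generation.
#' @param seed integer RNG seed; generation is deterministic given the
#'   seed.
#' @return A `truth_params` list, validated.
#' @export
truth_params <- function(n = 4137L,
                         n_strata = 14L,
                         psu_per_stratum = 2L,
                         weight_range = c(5000, 80000),
                         alpha_m = log(1.32),
                         beta_m = log(1.34),
                         gamma_direct = log(1.50),
                         mma_curvature = 0.6,
                         covariate_effects = c(age = 0.05,
                                               diabetes = log(1.8),
                                               dyslipidemia = log(1.5)),
                         baseline_prevalence = 0.20,
                         missing_rates = c(education = 0.04,
                                           wbc = 0.03,
                                           vitamin_b12 = 0.05),
                         seed = 1L) {
  p <- list(n = as.integer(n), n_strata = as.integer(n_strata),
            psu_per_stratum = as.integer(psu_per_stratum),
            weight_range = as.numeric(weight_range),
            alpha_m = alpha_m, beta_m = beta_m,
            gamma_direct = gamma_direct,
            mma_curvature = mma_curvature,
            covariate_effects = covariate_effects,
            baseline_prevalence = baseline_prevalence,
            missing_rates = missing_rates,
            seed = as.integer(seed))
  class(p) <- "truth_params"
  validate_truth_params(p)
  p
}

validate_truth_params <- function(p) {
  fail <- function(field, msg)
    stop(sprintf("invalid truth_params$%s: %s", field, msg), call. = FALSE)
  if (is.na(p$n) || p$n < 0L) fail("n", "must be a non-negative integer")
  if (p$n_strata < 1L) fail("n_strata", "must be positive")
  if (p$psu_per_stratum < 1L) fail("psu_per_stratum", "must be positive")
  if (length(p$weight_range) != 2L || any(p$weight_range <= 0) ||
      p$weight_range[1] > p$weight_range[2])
    fail("weight_range", "must be an increasing pair of positive reals")
  for (f in c("alpha_m", "beta_m", "gamma_direct"))
    if (!is.finite(p[[f]])) fail(f, "must be finite")
  if (!is.finite(p$mma_curvature) || p$mma_curvature < 0)
    fail("mma_curvature", "must be a finite non-negative real")
  if (!is.numeric(p$covariate_effects) ||
      (length(p$covariate_effects) && is.null(names(p$covariate_effects))))
    fail("covariate_effects", "must be a named numeric vector")
  if (p$baseline_prevalence <= 0 || p$baseline_prevalence >= 1)
    fail("baseline_prevalence", "must lie in (0, 1)")
  if (length(p$missing_rates)) {
    if (is.null(names(p$missing_rates)))
      fail("missing_rates", "must be named")
    if (any(p$missing_rates < 0) || any(p$missing_rates >= 1))
      fail("missing_rates", "rates must lie in [0, 1)")
  }
  if (is.na(p$seed)) fail("seed", "must be an integer")
  invisible(p)
}

# median intakes (reference gender: male) used as log-normal location
# parameters for the 16 dietary components; female locations are shifted
# down by 0.2 on the log scale.  Values are typical adult daily intakes.
dietary_medians <- c(
  d_fiber = 17, d_carotene = 9000, d_riboflavin = 2.2, d_niacin = 25,
  d_vitamin_b6 = 2.0, d_total_folate = 400, d_vitamin_b12 = 4.5,
  d_vitamin_c = 70, d_vitamin_e = 8, d_calcium = 950, d_magnesium = 300,
  d_zinc = 11, d_copper = 1.2, d_selenium = 110,
  d_total_fat = 80, d_iron = 14)

#' Column schema of a synthetic cohort table
#'
#' @return Character vector of column names, in order.  The last two
#'   columns (`low_obs_true`, `mma_high_true`) are latent ground-truth
#'   indicators kept for oracle checks; they are not observed data.
#' @export
cohort_schema <- function() {
  c("id", "age", "gender", "race", "education", "pir_group", "diabetes",
    "dyslipidemia", "wbc", "vitamin_b12", "energy", "weight", "stratum",
    "psu", names(dietary_medians), "met_score", "cotinine",
    "alcohol_g_day", "bmi", "mma", "cvd", "low_obs_true", "mma_high_true")
}

empty_cohort <- function() {
  out <- data.frame(
    id = integer(), age = numeric(),
    gender = factor(character(), levels = c("male", "female")),
    race = factor(character(), levels = race_levels()),
    education = factor(character(), levels = education_levels()),
    pir_group = factor(character(), levels = pir_levels()),
    diabetes = integer(), dyslipidemia = integer(), wbc = numeric(),
    vitamin_b12 = numeric(), energy = numeric(), weight = numeric(),
    stratum = integer(), psu = integer())
  for (nm in names(dietary_medians)) out[[nm]] <- numeric()
  out$met_score <- numeric(); out$cotinine <- numeric()
  out$alcohol_g_day <- numeric(); out$bmi <- numeric()
  out$mma <- numeric(); out$cvd <- integer()
  out$low_obs_true <- integer(); out$mma_high_true <- integer()
  out
}

race_levels <- function()
  c("mexican_american", "other_hispanic", "nh_white", "nh_black", "other")
education_levels <- function() c("below_high_school", "high_school", "college")
pir_levels <- function() c("<1", ">=1", "unknown")

#' Generate a synthetic hypertensive cohort with known mediation truth
#'
#' Draws an NHANES-like cohort under [truth_params()]: a two-stage design
#' (strata x PSUs with uniform per-person weights), gender-specific
#' log-normal dietary and lifestyle components, a latent low-OBS exposure
#' (first tertile of the computed OBS), serum MMA whose high/low state is
#' Bernoulli with log-odds shifted by `alpha_m` for low-OBS participants
#' (MMA values are drawn from the matching half of a log-normal centered
#' at 154.9 nmol/L, so the median split recovers the latent state), and a
#' CVD outcome from a logistic model with direct effect `gamma_direct`,
#' mediator effect `beta_m`, and the configured covariate effects, with
#' the intercept calibrated to the target prevalence.  MCAR missingness
#' is then injected per `missing_rates`.
#'
#' @param params a [truth_params()] object.
#' @return Data frame following [cohort_schema()], deterministic given
#'   `params$seed`.
#' @examples
#' cohort <- generate_cohort(truth_params(n = 500, seed = 42))
#' mean(cohort$cvd)
#' @export
generate_cohort <- function(params) {
  validate_truth_params(params)
  n <- params$n
  if (n == 0L) return(empty_cohort())
  with_seed(params$seed, {
    # two-stage design: every (stratum, PSU) cell non-empty when n allows
    n_cells <- params$n_strata * params$psu_per_stratum
    cell <- sample(rep_len(seq_len(n_cells), n))
    stratum <- (cell - 1L) %/% params$psu_per_stratum + 1L
    psu <- (cell - 1L) %% params$psu_per_stratum + 1L
    weight <- stats::runif(n, params$weight_range[1], params$weight_range[2])

    gender <- factor(sample(c("male", "female"), n, replace = TRUE),
                     levels = c("male", "female"))
    age <- pmin(pmax(round(stats::rnorm(n, 57, 12)), 20), 85)
    race <- factor(sample(race_levels(), n, replace = TRUE,
                          prob = c(0.094, 0.086, 0.439, 0.275, 0.106)),
                   levels = race_levels())
    education <- factor(sample(education_levels(), n, replace = TRUE,
                               prob = c(0.25, 0.24, 0.51)),
                        levels = education_levels())
    pir_group <- factor(sample(pir_levels(), n, replace = TRUE,
                               prob = c(0.20, 0.72, 0.08)),
                        levels = pir_levels())
    diabetes <- stats::rbinom(n, 1L, 0.32)
    dyslipidemia <- stats::rbinom(n, 1L, 0.83)
    wbc <- pmax(stats::rnorm(n, 7.35, 2.0), 1.5)
    vitamin_b12 <- stats::rlnorm(n, log(440), 0.40)
    energy <- stats::rlnorm(n, log(2000), 0.35)

    cohort <- data.frame(id = seq_len(n), age = age, gender = gender,
                         race = race, education = education,
                         pir_group = pir_group, diabetes = diabetes,
                         dyslipidemia = dyslipidemia, wbc = wbc,
                         vitamin_b12 = vitamin_b12, energy = energy,
                         weight = weight, stratum = stratum, psu = psu)
    shift <- ifelse(gender == "female", -0.2, 0)
    for (nm in names(dietary_medians))
      cohort[[nm]] <- stats::rlnorm(n, log(dietary_medians[[nm]]) + shift, 0.5)
    cohort$met_score <- stats::rlnorm(n, log(600) + shift, 0.9)
    smoker <- stats::rbinom(n, 1L, 0.25)
    cohort$cotinine <- ifelse(smoker == 1L,
                              stats::rlnorm(n, log(150), 0.8),
                              stats::rlnorm(n, log(0.05), 1.0))
    drinker <- stats::rbinom(n, 1L, 0.6)
    cohort$alcohol_g_day <- drinker *
      stats::rlnorm(n, ifelse(gender == "female", log(4), log(8)), 1.0)
    cohort$bmi <- stats::rlnorm(n, log(29), 0.18)

    # latent exposure: first tertile of the OBS computed on this cohort
    obs <- compute_obs(cohort)
    grp <- dichotomize_obs(obs$obs_total)
    low <- as.integer(grp == "low")
    cohort$low_obs_true <- low

    # latent high-MMA state: P(high) shifted by alpha_m for low OBS,
    # calibrated so the marginal P(high) is 1/2 (the median split)
    f <- mean(low)
    eta0 <- if (abs(params$alpha_m) < 1e-12) 0 else
      stats::uniroot(function(e)
        f * stats::plogis(e + params$alpha_m) + (1 - f) * stats::plogis(e) - 0.5,
        c(-20, 20))$root
    p_high <- stats::plogis(eta0 + params$alpha_m * low)
    high <- stats::rbinom(n, 1L, p_high)
    cohort$mma_high_true <- high
    # MMA drawn from the half of a log-normal matching the latent state
    z <- abs(stats::rnorm(n)) * ifelse(high == 1L, 1, -1)
    cohort$mma <- exp(log(154.9) + 0.45 * z)

    # outcome: direct + mediator + U-shaped log-MMA curvature + covariate
    # effects, intercept calibrated to the target prevalence
    lp <- params$gamma_direct * low + params$beta_m * high +
      params$mma_curvature * (log(cohort$mma) - log(154.9))^2
    for (nm in names(params$covariate_effects)) {
      if (!nm %in% names(cohort))
        stop("covariate_effects names unknown column: ", nm, call. = FALSE)
      x <- cohort[[nm]]
      x <- if (is.numeric(x) && length(unique(x)) > 2L) x - mean(x)
           else as.numeric(x)
      lp <- lp + params$covariate_effects[[nm]] * x
    }
    b0 <- stats::uniroot(function(b)
      mean(stats::plogis(b + lp)) - params$baseline_prevalence,
      c(-30, 30))$root
    cohort$cvd <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))
    cohort <- cohort[, cohort_schema()]

    if (length(params$missing_rates))
      cohort <- inject_missingness(cohort, params$missing_rates,
                                   mechanism = "MCAR", seed = NULL)
    cohort
  })
}

#' Inject missing-completely-at-random values
#'
#' Replaces a random fraction of each named column with `NA`, leaving all
#' other cells untouched.
#'
#' @param cohort data frame.
#' @param rates named vector of missingness fractions in `[0, 1)`.
#' @param mechanism only `"MCAR"` is supported.
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return The cohort with missing cells injected.
#' @export
inject_missingness <- function(cohort, rates, mechanism = "MCAR",
                               seed = NULL) {
  mechanism <- match.arg(mechanism, "MCAR")
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown))
    stop("missingness rate for unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(rates < 0) || any(rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    for (nm in names(rates)) {
      if (rates[[nm]] == 0) next
      mask <- stats::runif(nrow(cohort)) < rates[[nm]]
      cohort[[nm]][mask] <- NA
    }
    cohort
  })
}
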