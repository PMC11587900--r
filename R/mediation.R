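#' Estimate the mediation path coefficients a, b, c, c'
#'
#' Three survey-weighted logistic regressions on the same analytic rows:
#' the total effect `c` from `outcome ~ exposure + covariates`, path `a`
#' from `mediator ~ exposure + covariates`, and paths `b` (mediator on
#' outcome) and `c'` (direct effect) from
#' `outcome ~ exposure + mediator + covariates`.  All coefficients are
#' log-odds ratios with design-based (Taylor-linearized) standard errors.
#'
#' @param exposure,mediator,outcome column names of binary variables in
#'   the design's data (factors use their second level as the index
#'   category).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param design a [svy_design()] object.
#' @param align_rows restrict all three fits to rows complete in every
#'   model variable (default `TRUE`); with `FALSE`, differing analytic
#'   samples across fits raise an error.
#' @param single_psu see [svy_logit()].
#' @return List with elements `a`, `b`, `c`, `c_prime` (each
#'   `c(est, se)`), the three fits, and `n`.
#' @export
estimate_paths <- function(exposure, mediator, outcome,
                           covariates = character(), design,
                           align_rows = TRUE,
                           single_psu = c("fail", "center")) {
  stopifnot(inherits(design, "svy_design"))
  single_psu <- match.arg(single_psu)
  vars <- c(outcome, exposure, mediator, covariates)
  missing_cols <- setdiff(vars, names(design$data))
  if (length(missing_cols))
    stop("columns not in design data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (align_rows) {
    cc <- stats::complete.cases(design$data[, vars, drop = FALSE])
    design <- subset_design(design, cc)
  }
  f_c <- stats::reformulate(c(exposure, covariates), response = outcome)
  f_a <- stats::reformulate(c(exposure, covariates), response = mediator)
  f_b <- stats::reformulate(c(exposure, mediator, covariates),
                            response = outcome)
  fit_c <- svy_logit(f_c, design, single_psu = single_psu)
  fit_a <- svy_logit(f_a, design, single_psu = single_psu)
  fit_b <- svy_logit(f_b, design, single_psu = single_psu)
  if (!align_rows &&
      (fit_c$n != fit_a$n || fit_c$n != fit_b$n))
    stop("analytic samples differ across the three path models; ",
         "use align_rows = TRUE to take their intersection", call. = FALSE)

  term_of <- function(fit, var) {
    nm <- names(coef(fit))
    hit <- nm[startsWith(nm, var) & nm != "(Intercept)"]
    if (length(hit) != 1L)
      stop("could not identify a single coefficient for '", var, "'",
           call. = FALSE)
    hit
  }
  grab <- function(fit, var) {
    tm <- term_of(fit, var)
    c(est = unname(coef(fit)[tm]), se = sqrt(vcov(fit)[tm, tm]))
  }
  list(a = grab(fit_a, exposure),
       b = grab(fit_b, mediator),
       c = grab(fit_c, exposure),
       c_prime = grab(fit_b, exposure),
       fit_total = fit_c, fit_mediator = fit_a, fit_outcome = fit_b,
       n = fit_c$n)
}

#' Distribution-of-product confidence interval for an indirect effect
#'
#' Confidence limits for the product of two path coefficients from the
#' distribution of `Z1 * Z2` with `Z1 ~ N(a, se_a^2)` and
#' `Z2 ~ N(b, se_b^2)` independent, computed by seeded Monte Carlo.  The
#' analytic Sobel (delta-method) interval
#' `ab +/- z * sqrt(a^2 se_b^2 + b^2 se_a^2)` is attached for comparison;
#' the two agree when both paths are many standard errors from zero.
#'
#' @param a,se_a estimate and SE of the exposure-to-mediator path.
#' @param b,se_b estimate and SE of the mediator-to-outcome path.
#' @param alpha two-sided error rate (default 0.05).
#' @param draws Monte Carlo draws (default 1e6; below 1e4 a warning is
#'   issued).
#' @param seed integer seed making the interval reproducible, or `NULL`
#'   for the current RNG stream.
#' @return Numeric `c(lower, upper)` with attributes `estimate` (`a*b`)
#'   and `sobel` (the delta-method interval).
#' @export
distribution_of_product_ci <- function(a, se_a, b, se_b, alpha = 0.05,
                                       draws = 1e6, seed = NULL) {
  vals <- c(a = a, se_a = se_a, b = b, se_b = se_b, alpha = alpha)
  if (any(!is.finite(vals))) stop("non-finite inputs", call. = FALSE)
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive",
                                   call. = FALSE)
  if (draws < 1e4)
    warning("fewer than 10^4 draws: interval will be noisy", call. = FALSE)
  prod_draws <- with_seed(seed, {
    stats::rnorm(draws, a, se_a) * stats::rnorm(draws, b, se_b)
  })
  ci <- unname(stats::quantile(prod_draws, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  zq <- stats::qnorm(1 - alpha / 2)
  se_sobel <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  structure(ci, estimate = a * b,
            sobel = c(a * b - zq * se_sobel, a * b + zq * se_sobel))
}

#' Mediated proportion on the log-OR scale
#'
#' The ratio of the indirect effect to the total effect,
#' `ab / c`, both on the log-odds-ratio scale.  When the indirect and
#' total effects disagree in sign the ratio is returned with an
#' `inconsistent` attribute (suppression), since a "proportion" reading
#' is then meaningless.
#'
#' @param ab indirect-effect estimate (product of paths).
#' @param c total-effect log-OR; must be nonzero.
#' @return The fraction `ab / c` (multiply by 100 for percent), possibly
#'   carrying attribute `inconsistent = TRUE`.
#' @examples
#' # worked example from published mediation output: indirect estimate
#' # 0.071 against a total-effect OR of 1.61 gives 14.9%
#' round(100 * mediated_proportion(0.071, log(1.61)), 1)
#' @export
mediated_proportion <- function(ab, c) {
  if (!is.finite(ab) || !is.finite(c)) stop("non-finite inputs")
  if (c == 0) stop("total effect is zero: mediated proportion undefined")
  out <- ab / c
  if (ab != 0 && sign(ab) != sign(c)) {
    warning("indirect and total effects have opposite signs ",
            "(suppression); proportion flagged inconsistent",
            call. = FALSE)
    attr(out, "inconsistent") <- TRUE
  }
  out
}

#' Run a full mediation analysis, optionally by subgroup
#'
#' Estimates paths, the distribution-of-product interval, the indirect
#' OR, the mediated proportion, and the log-scale decomposition
#' diagnostic `|c - (c' + ab)|` (which is near zero only for rare
#' outcomes, and is always reported) for the total sample and for each
#' level of an optional subgroup column.  Subgroup fits refit all three
#' models within the level; degenerate levels (constant outcome,
#' exposure, or mediator) are skipped with a message.
#'
#' @inheritParams estimate_paths
#' @param subgroups optional name of a categorical column to stratify on.
#' @param draws,seed,alpha passed to [distribution_of_product_ci()]; each
#'   stratum uses an offset of `seed` so results are reproducible.
#' @return An object of class `mediation_result`: a list of per-stratum
#'   records (`label`, `n`, paths, `ab`, `ab_ci`, `sobel_ci`,
#'   `indirect_or`, `indirect_or_ci`, `proportion_mediated`,
#'   `total_or`, `direct_or`, `decomposition_gap`).
#' @export
run_mediation <- function(exposure, mediator, outcome,
                          covariates = character(), design,
                          subgroups = NULL, alpha = 0.05, draws = 1e6,
                          seed = NULL, align_rows = TRUE,
                          single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  one_sub <- function(des, label, covs, seed_k) {
    paths <- estimate_paths(exposure, mediator, outcome, covs,
                            des, align_rows = align_rows,
                            single_psu = single_psu)
    ab <- paths$a[["est"]] * paths$b[["est"]]
    ci <- distribution_of_product_ci(paths$a[["est"]], paths$a[["se"]],
                                     paths$b[["est"]], paths$b[["se"]],
                                     alpha = alpha, draws = draws,
                                     seed = seed_k)
    prop <- suppressWarnings(mediated_proportion(ab, paths$c[["est"]]))
    list(label = label, n = paths$n,
         a = paths$a, b = paths$b, c = paths$c, c_prime = paths$c_prime,
         ab = ab, ab_ci = as.numeric(ci),
         sobel_ci = attr(ci, "sobel"),
         indirect_or = exp(ab), indirect_or_ci = exp(as.numeric(ci)),
         proportion_mediated = prop,
         total_or = exp(paths$c[["est"]]),
         direct_or = exp(paths$c_prime[["est"]]),
         decomposition_gap = abs(paths$c[["est"]] -
                                   (paths$c_prime[["est"]] + ab)),
         mediation_present = prod(as.numeric(ci)) > 0)
  }
  one <- function(des, label, seed_k) one_sub(des, label, covariates, seed_k)
  res <- list(one(design, "total", seed))
  if (!is.null(subgroups)) {
    if (!subgroups %in% names(design$data))
      stop("subgroup column not found: ", subgroups, call. = FALSE)
    gv <- design$data[[subgroups]]
    lv <- if (is.factor(gv)) levels(droplevels(gv)) else sort(unique(gv[!is.na(gv)]))
    for (k in seq_along(lv)) {
      idx <- !is.na(gv) & gv == lv[k]
      des_k <- subset_design(design, idx)
      # the stratifying variable is constant within a level and must
      # leave the covariate set of the refits
      covs_k <- setdiff(covariates, subgroups)
      rec <- tryCatch(
        one_sub(des_k, paste0(subgroups, "=", lv[k]), covs_k,
                if (is.null(seed)) NULL else seed + k),
        error = function(e) {
          message(sprintf("subgroup %s=%s skipped: %s",
                          subgroups, lv[k], conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) res <- c(res, list(rec))
    }
  }
  structure(res, class = "mediation_result",
            exposure = exposure, mediator = mediator, outcome = outcome)
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation of %s -> %s -> %s (log-OR scale paths)\n\n",
              attr(x, "exposure"), attr(x, "mediator"), attr(x, "outcome")))
  tab <- as.data.frame(x)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    population = r$label, n = r$n,
    total_or = r$total_or, direct_or = r$direct_or,
    dop_beta = r$ab, dop_lower = r$ab_ci[1], dop_upper = r$ab_ci[2],
    indirect_or = r$indirect_or,
    indirect_or_lower = r$indirect_or_ci[1],
    indirect_or_upper = r$indirect_or_ci[2],
    mediated_pct = 100 * as.numeric(r$proportion_mediated),
    decomposition_gap = r$decomposition_gap,
    mediation_present = r$mediation_present)))
}
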