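#' The oxidative balance score component registry
#'
#' The OBS sums points over 20 components: 16 dietary and 4 lifestyle,
#' of which 5 are pro-oxidants (total fat, total iron intake, tobacco
#' exposure measured as serum cotinine, alcohol consumption, and BMI) and
#' 15 antioxidants.  Every component except alcohol is scored by
#' gender-specific tertiles: antioxidants score 0/1/2 from the lowest to
#' the highest tertile, pro-oxidants 2/1/0.  Alcohol is scored by
#' categorical drinking status with gender-specific thresholds.
#'
#' The default dietary set (fiber, carotene, riboflavin, niacin, vitamin
#' B6, total folate, vitamin B12, vitamin C, vitamin E, calcium,
#' magnesium, zinc, copper, selenium as antioxidants; total fat and iron
#' as pro-oxidants) follows the commonly used OBS scheme for NHANES
#' dietary recall data.  The registry is the source of truth and can be
#' replaced by a YAML file with the same fields; any registry is
#' validated against the 16 dietary / 4 lifestyle and 5 pro- / 15
#' antioxidant count invariants.
#'
#' @param path optional path to a YAML registry (a list of records with
#'   fields `name`, `class`, `direction`, `scoring`).
#' @return Data frame with columns `name`, `class` (`dietary`/`lifestyle`),
#'   `direction` (`antioxidant`/`prooxidant`), `scoring` (`tertile`/
#'   `alcohol_category`).
#' @export
obs_registry <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    reg <- do.call(rbind, lapply(raw, function(r)
      data.frame(name = r$name, class = r$class, direction = r$direction,
                 scoring = r$scoring)))
  } else {
    anti_diet <- c("d_fiber", "d_carotene", "d_riboflavin", "d_niacin",
                   "d_vitamin_b6", "d_total_folate", "d_vitamin_b12",
                   "d_vitamin_c", "d_vitamin_e", "d_calcium",
                   "d_magnesium", "d_zinc", "d_copper", "d_selenium")
    reg <- rbind(
      data.frame(name = anti_diet, class = "dietary",
                 direction = "antioxidant", scoring = "tertile"),
      data.frame(name = c("d_total_fat", "d_iron"), class = "dietary",
                 direction = "prooxidant", scoring = "tertile"),
      data.frame(name = "met_score", class = "lifestyle",
                 direction = "antioxidant", scoring = "tertile"),
      data.frame(name = c("cotinine", "bmi"), class = "lifestyle",
                 direction = "prooxidant", scoring = "tertile"),
      data.frame(name = "alcohol_g_day", class = "lifestyle",
                 direction = "prooxidant", scoring = "alcohol_category"))
  }
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  req <- c("name", "class", "direction", "scoring")
  if (!all(req %in% names(reg)))
    stop("registry must have fields ", paste(req, collapse = ", "))
  if (anyDuplicated(reg$name)) stop("duplicate component names in registry")
  n_diet <- sum(reg$class == "dietary")
  n_life <- sum(reg$class == "lifestyle")
  if (n_diet != 16L || n_life != 4L)
    stop(sprintf("registry must hold 16 dietary + 4 lifestyle components (got %d + %d)",
                 n_diet, n_life))
  n_pro <- sum(reg$direction == "prooxidant")
  if (n_pro != 5L || sum(reg$direction == "antioxidant") != 15L)
    stop(sprintf("registry must hold 5 prooxidant and 15 antioxidant components (got %d prooxidant)",
                 n_pro))
  if (sum(reg$scoring == "alcohol_category") != 1L)
    stop("exactly one component must use alcohol_category scoring")
  invisible(reg)
}

#' Write the component registry to YAML
#'
#' @param reg a registry data frame (see [obs_registry()]).
#' @param path output file path.
#' @export
write_registry <- function(reg, path) {
  validate_registry(reg)
  yaml::write_yaml(
    lapply(seq_len(nrow(reg)), function(i) as.list(reg[i, ])), path)
  invisible(path)
}

#' Gender-specific tertile cutoffs
#'
#' Computes, within each gender, the 1/3 and 2/3 empirical quantiles
#' (inverse-ECDF, quantile type 1) of a component.  Tertile membership
#' downstream uses the deterministic tie rule "value <= cutoff falls in the
#' lower tertile", so for values 1..9 the cutoffs are (3, 6) and the
#' tertiles have sizes 3/3/3.
#'
#' @param values numeric vector.
#' @param gender factor-like vector with exactly two levels, aligned with
#'   `values`.
#' @return Data frame with columns `gender`, `lower`, `upper`.
#' @export
gender_tertiles <- function(values, gender) {
  g <- droplevels(factor(gender))
  if (nlevels(g) > 2L) stop("gender must have at most two levels")
  out <- lapply(levels(g), function(lv) {
    x <- values[g == lv & !is.na(values)]
    if (length(x) < 3L)
      stop("need at least 3 non-missing values per gender stratum")
    if (length(unique(x)) == 1L)
      stop("degenerate tertile cutoffs: all values identical in a gender stratum")
    q <- quantile1(x, c(1 / 3, 2 / 3))
    data.frame(gender = lv, lower = q[1], upper = q[2])
  })
  do.call(rbind, out)
}

#' Score one tertile-based component
#'
#' Maps values to OBS points given tertile cutoffs: antioxidants score
#' 0/1/2 and pro-oxidants 2/1/0 from the lowest to the highest tertile.
#' Values equal to a cutoff fall in the lower tertile (<= rule).  Missing
#' values yield missing points (the participant is later excluded from
#' the score).
#'
#' @param value numeric vector.
#' @param lower,upper tertile cutoffs (scalars).
#' @param direction `"antioxidant"` or `"prooxidant"`.
#' @return Integer points in `{0, 1, 2}` (NA for missing input).
#' @export
score_component <- function(value, lower, upper,
                            direction = c("antioxidant", "prooxidant")) {
  direction <- match.arg(direction)
  if (lower > upper) stop("lower cutoff exceeds upper cutoff")
  tert <- ifelse(value <= lower, 1L, ifelse(value <= upper, 2L, 3L))
  if (direction == "antioxidant") tert - 1L else 3L - tert
}

#' Score the alcohol component
#'
#' Alcohol is the one OBS component not scored by tertiles: nondrinkers
#' (exactly 0 g/day) score 2 points, moderate drinkers 1 point, and heavy
#' drinkers 0 points, with the heavy threshold at >= 15 g/day for women
#' and >= 30 g/day for men.
#'
#' @param grams_per_day non-negative numeric vector.
#' @param gender vector with values `"male"`/`"female"`.
#' @return Integer points in `{0, 1, 2}` (NA for missing intake).
#' @export
score_alcohol <- function(grams_per_day, gender) {
  if (any(grams_per_day < 0, na.rm = TRUE))
    stop("negative alcohol intake")
  g <- as.character(gender)
  if (!all(g[!is.na(g)] %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  thr <- ifelse(g == "female", 15, 30)
  ifelse(is.na(grams_per_day) | is.na(g), NA_integer_,
         ifelse(grams_per_day == 0, 2L,
                ifelse(grams_per_day < thr, 1L, 0L)))
}

#' Compute the oxidative balance score
#'
#' Scores every registry component for every participant and sums the
#' points.  Tertile cutoffs are computed within gender on the supplied
#' cohort (unweighted empirical quantiles).  Participants missing any
#' component receive no total and are flagged `excluded`.
#'
#' @param cohort data frame holding all 20 component columns and a
#'   two-level `gender` column.
#' @param registry component registry (default [obs_registry()]).
#' @return Data frame with one `pts_<component>` column per component,
#'   `obs_total` (in `[0, 40]`), and `excluded`; tertile cutoffs are
#'   attached as attribute `"cutoffs"`.
#' @examples
#' cohort <- generate_cohort(truth_params(n = 200, seed = 7))
#' obs <- compute_obs(cohort)
#' range(obs$obs_total, na.rm = TRUE)
#' @export
compute_obs <- function(cohort, registry = obs_registry()) {
  validate_registry(registry)
  missing_cols <- setdiff(registry$name, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"gender" %in% names(cohort)) stop("cohort is missing 'gender'")
  g <- droplevels(factor(cohort$gender))

  pts <- matrix(NA_integer_, nrow(cohort), nrow(registry),
                dimnames = list(NULL, paste0("pts_", registry$name)))
  cuts <- list()
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    x <- cohort[[nm]]
    if (registry$scoring[i] == "alcohol_category") {
      pts[, i] <- score_alcohol(x, cohort$gender)
    } else {
      ct <- gender_tertiles(x, g)
      cuts[[nm]] <- ct
      for (j in seq_len(nrow(ct))) {
        sel <- !is.na(g) & g == ct$gender[j]
        pts[sel, i] <- score_component(x[sel], ct$lower[j], ct$upper[j],
                                       registry$direction[i])
      }
    }
  }
  total <- rowSums(pts)
  out <- as.data.frame(pts)
  out$obs_total <- total
  out$excluded <- is.na(total)
  attr(out, "cutoffs") <- cuts
  out
}

#' Dichotomize the OBS into low/high exposure groups
#'
#' The exposure contrast is the first score tertile against the upper two:
#' `low` iff `obs_total < cutoff`, with ties at the cutoff going to `high`
#' (a total exactly equal to the cutoff is high).  By default the cutoff
#' is recomputed as the first tertile (1/3 quantile) of the totals in the
#' analytic sample rather than fixed at any particular published value.
#'
#' @param obs_total numeric vector of OBS totals.
#' @param cutoff dichotomization cutoff; `NULL` (default) recomputes the
#'   1/3 quantile of the non-missing totals.
#' @return Factor with levels `c("high", "low")` (`high` is the reference
#'   level for regression) and the cutoff attached as attribute
#'   `"cutoff"`.
#' @export
dichotomize_obs <- function(obs_total, cutoff = NULL) {
  if (is.null(cutoff))
    cutoff <- quantile1(obs_total[!is.na(obs_total)], 1 / 3)
  out <- factor(ifelse(obs_total < cutoff, "low", "high"),
                levels = c("high", "low"))
  attr(out, "cutoff") <- cutoff
  out
}
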