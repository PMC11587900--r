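#' Restricted cubic spline basis
#'
#' Builds the restricted (natural) cubic spline basis in the truncated
#' power parameterization: with knots `t_1 < ... < t_k` the basis has
#' `k - 1` columns (the linear term plus `k - 2` restricted cubic terms),
#' and any linear combination is linear beyond the boundary knots.  The
#' cubic terms are scaled by `(t_k - t_1)^2` so coefficients share the
#' scale of the linear term.
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector of 3 to 5 knots.
#' @return Matrix with `length(knots) - 1` columns and attribute
#'   `"knots"`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3L || k > 5L) stop("knot count must be 3, 4, or 5")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  tau2 <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1] <- x
  for (j in seq_len(k - 2L)) {
    B[, j + 1L] <- (cube(x - knots[j]) -
      cube(x - knots[k - 1L]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1L]) +
      cube(x - knots[k]) * (knots[k - 1L] - knots[j]) /
        (knots[k] - knots[k - 1L])) / tau2
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2L)))
  attr(B, "knots") <- knots
  B
}

# standard percentile placements for k knots
default_knots <- function(x, n_knots = 4L) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("knot count must be 3, 4, or 5"))
  kn <- unname(stats::quantile(x, probs, na.rm = TRUE))
  if (any(diff(kn) <= 0))
    stop("degenerate knot placement (ties in the predictor quantiles)")
  kn
}

#' Restricted-cubic-spline logistic dose-response fit
#'
#' Fits a survey-weighted logistic regression of a binary outcome on the
#' restricted cubic spline expansion of a continuous predictor plus
#' optional covariates, then tests the overall association (all spline
#' terms jointly) and nonlinearity (the cubic terms only) with
#' design-consistent Wald tests.
#'
#' @param y binary outcome vector aligned with the design rows.
#' @param x continuous predictor vector.
#' @param covariates optional character vector of covariate column names
#'   in the design's data.
#' @param design a [svy_design()] object.
#' @param n_knots number of knots (3-5) placed at standard percentiles,
#'   ignored when `knots` is given.
#' @param knots optional explicit knot vector.
#' @param single_psu see [svy_logit()].
#' @return An object of class `rcs_fit`: the underlying `svy_logit` fit,
#'   `knots`, `p_overall`, `p_nonlinear`, and the spline coefficient
#'   names.
#' @seealso [find_inflection()], [choose_cutoff()]
#' @export
fit_rcs_logistic <- function(y, x, covariates = NULL, design,
                             n_knots = 4L, knots = NULL,
                             single_psu = c("fail", "center")) {
  stopifnot(inherits(design, "svy_design"))
  single_psu <- match.arg(single_psu)
  if (is.null(knots)) knots <- default_knots(x, n_knots)
  if (length(unique(x[!is.na(x)])) < length(knots))
    stop("predictor has fewer distinct values than knots")
  B <- rcs_basis(x, knots)
  dat <- design$data
  dat$.y <- y
  spline_terms <- paste0(".rcs_", colnames(B))
  for (j in seq_along(spline_terms)) dat[[spline_terms[j]]] <- B[, j]
  d2 <- svy_design(dat)
  d2$weights <- design$weights
  d2$strata <- design$strata
  d2$psu <- design$psu
  rhs <- c(spline_terms, covariates)
  fit <- svy_logit(stats::reformulate(rhs, response = ".y"), d2,
                   single_psu = single_psu)
  nl_terms <- spline_terms[-1]
  structure(list(
    fit = fit,
    knots = knots,
    spline_terms = spline_terms,
    p_overall = wald_test(fit, spline_terms)$p,
    p_nonlinear = wald_test(fit, nl_terms)$p,
    x_range = range(x, na.rm = TRUE)
  ), class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat("Restricted-cubic-spline logistic fit\n")
  cat("  knots:", paste(signif(x$knots, 6), collapse = ", "), "\n")
  cat(sprintf("  p (overall association) = %.4g\n", x$p_overall))
  cat(sprintf("  p (nonlinearity)        = %.4g\n", x$p_nonlinear))
  invisible(x)
}

# fitted spline contribution to the log-odds over a grid (covariates and
# intercept only shift the curve, so slope/shape are unaffected)
rcs_curve <- function(object, grid) {
  B <- rcs_basis(grid, object$knots)
  drop(B %*% coef(object$fit)[object$spline_terms])
}

#' Locate the inflection point of a fitted spline curve
#'
#' Evaluates the fitted log-odds curve on a uniform grid between the
#' boundary knots and returns the predictor value where the numerical
#' first derivative changes sign.  If the derivative changes sign more
#' than once the first crossing is returned and all are recorded in the
#' `"all"` attribute; derivative magnitudes below `tol` are treated as
#' plateaus, not crossings.  Returns `NA` when the curve is monotone.
#'
#' @param result an `rcs_fit` object.
#' @param grid_size number of grid points (default 512).
#' @param tol slope magnitude below which a derivative is treated as
#'   zero.
#' @return The inflection abscissa (or `NA`), with attribute `"all"`
#'   listing every crossing.
#' @export
find_inflection <- function(result, grid_size = 512L, tol = 1e-8) {
  stopifnot(inherits(result, "rcs_fit"))
  k <- result$knots
  grid <- seq(k[1], k[length(k)], length.out = grid_size)
  eta <- rcs_curve(result, grid)
  d1 <- diff(eta) / diff(grid)
  s <- sign(d1)
  s[abs(d1) < tol] <- 0
  nz <- which(s != 0)
  crossings <- numeric(0)
  if (length(nz) > 1L) {
    sv <- s[nz]
    flips <- which(sv[-1] != sv[-length(sv)])
    for (f in flips) {
      i <- nz[f]; j <- nz[f + 1L]
      crossings <- c(crossings, (grid[i + 1L] + grid[j]) / 2)
    }
  }
  if (!length(crossings)) {
    out <- NA_real_
  } else {
    if (length(crossings) > 1L)
      message(sprintf(
        "find_inflection: %d sign changes; returning the first (all: %s)",
        length(crossings), paste(signif(crossings, 6), collapse = ", ")))
    out <- crossings[1]
  }
  attr(out, "all") <- crossings
  out
}

#' Choose the mediator dichotomization cutoff from an inflection point
#'
#' Implements the "closest interpretable value" rule: under policy
#' `nearest_quantile_median` the sample median is returned whenever it
#' lies within `tol_frac` of the IQR from the inflection point (the
#' situation where the inflection "corresponds to the median"), otherwise
#' the inflection itself is returned with a message.  Policy
#' `inflection_exact` always returns the inflection.
#'
#' @param inflection inflection abscissa (from [find_inflection()]).
#' @param x the predictor sample.
#' @param policy `"nearest_quantile_median"` (default) or
#'   `"inflection_exact"`.
#' @param tol_frac tolerance as a fraction of the IQR (default 0.10).
#' @return The chosen cutoff.
#' @export
choose_cutoff <- function(inflection, x,
                          policy = c("nearest_quantile_median",
                                     "inflection_exact"),
                          tol_frac = 0.10) {
  policy <- match.arg(policy)
  if (is.na(inflection)) stop("no inflection point to choose a cutoff from")
  if (policy == "inflection_exact") return(as.numeric(inflection))
  med <- stats::median(x, na.rm = TRUE)
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (abs(med - inflection) <= tol_frac * iqr) {
    med
  } else {
    message(sprintf(
      "choose_cutoff: median %.4g is not within %.0f%% of IQR of the inflection %.4g; using the inflection",
      med, 100 * tol_frac, inflection))
    as.numeric(inflection)
  }
}

#' @export
plot.rcs_fit <- function(x, grid_size = 200L, level = 0.95, ...) {
  k <- x$knots
  grid <- seq(k[1], k[length(k)], length.out = grid_size)
  B <- rcs_basis(grid, x$knots)
  beta <- coef(x$fit)[x$spline_terms]
  V <- vcov(x$fit)[x$spline_terms, x$spline_terms]
  eta <- drop(B %*% beta)
  se <- sqrt(rowSums((B %*% V) * B))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  graphics::plot(grid, eta, type = "l",
                 xlab = "predictor", ylab = "log-odds contribution", ...)
  graphics::lines(grid, eta - zq * se, lty = 2)
  graphics::lines(grid, eta + zq * se, lty = 2)
  graphics::rug(k)
  invisible(data.frame(x = grid, log_odds = eta, se = se))
}
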