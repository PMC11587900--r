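#' Survey-weighted logistic regression with design-based variance
#'
#' Fits a logistic regression by maximizing the weighted pseudo-likelihood
#' and estimates the coefficient covariance by Taylor-series linearization
#' over the design's (stratum, PSU) clusters, treating PSUs as drawn with
#' replacement within strata.  With all weights equal and one PSU per
#' observation in a single stratum the point estimates equal the ordinary
#' maximum-likelihood fit of [stats::glm()].
#'
#' Rows with missing values in any model variable are dropped
#' (complete-case within the fit); the rows actually used are recorded in
#' the returned object.  Weights are treated as sampling (probability)
#' weights: rescaling all weights by a positive constant changes no
#' estimate.
#'
#' @param formula model formula; the response must be binary (0/1, logical,
#'   or a two-level factor).
#' @param design a [svy_design()] object supplying data, weights and
#'   clustering.
#' @param single_psu how to handle strata with one PSU: `"fail"` (default)
#'   or `"center"` (center lonely PSUs at the grand mean).
#' @param epsilon,maxit IRLS convergence tolerance on the relative change
#'   in pseudo-deviance, and iteration cap.
#'
#' @return An object of class `svy_logit` with components `coefficients`,
#'   `vcov` (design-based), `naive_vcov` (inverse weighted information),
#'   `n`, `df_design`, `converged`, `separation`, `loglik` (weighted
#'   pseudo-log-likelihood), `fitted`, `linear_predictors`, `y`, `rows`
#'   (row indices of the design used), `formula`, `design_summary`.
#' @seealso [odds_ratios()], [wald_test()], [summary.svy_logit()]
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' d$y <- rbinom(500, 1, plogis(-1 + 0.8 * d$x))
#' fit <- svy_logit(y ~ x, svy_design(d))
#' coef(fit)
#' odds_ratios(fit)
#' @export
svy_logit <- function(formula, design, single_psu = c("fail", "center"),
                      epsilon = 1e-10, maxit = 30) {
  stopifnot(inherits(design, "svy_design"))
  single_psu <- match.arg(single_psu)
  mf <- stats::model.frame(formula, design$data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  rows <- seq_len(nrow(design$data))
  if (!is.null(dropped)) rows <- rows[-dropped]
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("response must have exactly two levels")
    y <- as.integer(y) - 1L
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  if (length(unique(y)) < 2L)
    stop("response is degenerate (all 0 or all 1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w <- design$weights[rows]
  # scale-invariance: normalize weights to mean 1 for the optimizer; the
  # estimating equations are homogeneous in w so estimates are unchanged
  wn <- w / mean(w)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("model matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    irls_w <- wn * mu * (1 - mu)
    zres <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, zres, irls_w)
    beta <- fit$coefficients
    dev <- -2 * sum(wn * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separation <- max(abs(beta)) > 15 ||
    all(abs(y - mu) < 1e-8)
  if (!converged || separation)
    warning("svy_logit: fit did not converge cleanly ",
            "(possible separation); estimates flagged", call. = FALSE)

  info <- crossprod(X, wn * mu * (1 - mu) * X)
  naive_vcov <- solve(info)
  scores <- X * (wn * (y - mu))           # weighted score contributions
  Vscore <- taylor_linearized_vcov(scores, design$strata[rows],
                                   design$psu[rows], single_psu = single_psu)
  V <- naive_vcov %*% Vscore %*% naive_vcov
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  dimnames(naive_vcov) <- dimnames(V)

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = V,
    naive_vcov = naive_vcov,
    n = length(y),
    df_design = nlevels(droplevels(design$psu[rows])) -
      nlevels(droplevels(design$strata[rows])),
    converged = converged && !separation,
    separation = separation,
    loglik = sum(wn * (y * log(pmax(mu, 1e-12)) +
                         (1 - y) * log(pmax(1 - mu, 1e-12)))),
    fitted = mu,
    linear_predictors = eta,
    y = y,
    prior_weights = w,
    rows = rows,
    formula = formula,
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    call = match.call()
  ), class = "svy_logit")
}

#' @export
print.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression (Taylor-linearized variance)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d, design df = %d%s\n", x$n, x$df_design,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.svy_logit <- function(object, ...) object$coefficients

#' @export
vcov.svy_logit <- function(object, ...) object$vcov

#' @export
logLik.svy_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Summarize a survey-weighted logistic fit
#'
#' @param object a [svy_logit()] fit.
#' @param df reference distribution for p-values: `"normal"` (default,
#'   large-sample) or `"design"` (t with design degrees of freedom,
#'   #PSUs - #strata).
#' @param ... unused.
#' @return A `summary.svy_logit` object whose `coefficients` matrix holds
#'   estimates, design-based SEs, test statistics and p-values.
#' @export
summary.svy_logit <- function(object, df = c("normal", "design"), ...) {
  df <- match.arg(df)
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- if (df == "normal") 2 * stats::pnorm(-abs(z))
       else 2 * stats::pt(-abs(z), df = max(object$df_design, 1))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = p)
  structure(list(coefficients = tab, n = object$n,
                 df_design = object$df_design, df = df,
                 converged = object$converged, call = object$call),
            class = "summary.svy_logit")
}

#' @export
print.summary.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d, design df = %d, %s reference\n", x$n,
              x$df_design, x$df))
  invisible(x)
}

#' @export
confint.svy_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.svy_logit <- function(object, newdata = NULL,
                              type = c("link", "response"),
                              se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictors
    X <- NULL
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  out <- if (type == "link") eta else stats::plogis(eta)
  if (!se.fit) return(out)
  if (is.null(X)) stop("se.fit requires newdata")
  se_eta <- sqrt(rowSums((X %*% object$vcov) * X))
  se <- if (type == "link") se_eta
        else se_eta * stats::plogis(eta) * (1 - stats::plogis(eta))
  list(fit = out, se.fit = se)
}

#' @export
residuals.svy_logit <- function(object,
                                type = c("response", "pearson", "working"),
                                ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  switch(type,
         response = r,
         pearson = r / sqrt(object$fitted * (1 - object$fitted)),
         working = r / (object$fitted * (1 - object$fitted)))
}

#' @export
simulate.svy_logit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed, {
    as.data.frame(replicate(
      nsim, stats::rbinom(object$n, 1L, object$fitted)))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Odds ratios with design-based confidence intervals
#'
#' Exponentiates the coefficients of a [svy_logit()] fit (or a Rubin-pooled
#' fit) and attaches Wald confidence limits `exp(coef +/- z * SE)` using the
#' design-based standard errors.
#'
#' @param fit a `svy_logit` or `rubin_pooled` object.
#' @param alpha two-sided error rate for the interval (default 0.05).
#' @param drop_intercept omit the intercept row (default `TRUE`).
#' @return Data frame with columns `term`, `or`, `lower`, `upper`, `p`.
#' @export
odds_ratios <- function(fit, alpha = 0.05, drop_intercept = TRUE) {
  if (inherits(fit, "svy_logit") && !fit$converged)
    warning("odds ratios from a non-converged fit", call. = FALSE)
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zq <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(
    term = names(b),
    or = exp(b),
    lower = exp(b - zq * se),
    upper = exp(b + zq * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    row.names = NULL)
  if (drop_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wald tests on fitted coefficients
#'
#' `wald_test()` performs a joint Wald chi-square test that a set of
#' coefficients is zero, using the design-based covariance.
#' `wald_interaction_test()` is the single-term version used for
#' exposure-by-mediator interaction rows: it returns the estimate, SE,
#' z statistic and two-sided normal p-value.
#'
#' @param fit a `svy_logit` fit.
#' @param terms character vector of coefficient names.
#' @return For `wald_test()`, a list with `statistic`, `df`, `p`; for
#'   `wald_interaction_test()`, a list with `estimate`, `se`, `z`, `p`.
#' @export
wald_test <- function(fit, terms) {
  b <- coef(fit)
  missing_terms <- setdiff(terms, names(b))
  if (length(missing_terms))
    stop("terms not in fit: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  bi <- b[terms]
  Vi <- vcov(fit)[terms, terms, drop = FALSE]
  stat <- drop(t(bi) %*% solve(Vi, bi))
  list(statistic = stat, df = length(terms),
       p = stats::pchisq(stat, df = length(terms), lower.tail = FALSE))
}

#' @rdname wald_test
#' @param term single coefficient name.
#' @export
wald_interaction_test <- function(fit, term) {
  b <- coef(fit)
  if (!term %in% names(b))
    stop("term not in fit: ", term, call. = FALSE)
  se <- sqrt(vcov(fit)[term, term])
  z <- b[[term]] / se
  list(estimate = b[[term]], se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
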