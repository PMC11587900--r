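#' Multiple imputation by chained regressions
#'
#' Fills missing values in the imputable columns (by default education,
#' WBC, and serum vitamin B12) with `m` independent completed datasets.
#' Each dataset is produced by chained univariate regression imputation:
#' continuous columns by normal-theory linear regression with parameter
#' and residual draws, categorical columns by multinomial logistic
#' regression ([nnet::multinom]) with category draws from the fitted
#' probabilities, cycled `cycles` times.  Observed cells are never
#' modified.
#'
#' @param cohort data frame.
#' @param m number of imputations (>= 1).
#' @param method only `"chained_regression"`.
#' @param seed integer seed, or `NULL` for the current stream.
#' @param columns columns eligible for imputation.
#' @param predictors complete columns used as predictors; defaults to the
#'   fully observed members of a standard covariate set.
#' @param cycles chained-equation cycles per dataset (default 10).
#' @return List of `m` completed data frames; if nothing is missing, `m`
#'   copies identical to the input.
#' @export
impute_missing <- function(cohort, m, method = "chained_regression",
                           seed = NULL,
                           columns = c("education", "wbc", "vitamin_b12"),
                           predictors = NULL, cycles = 10L) {
  method <- match.arg(method, "chained_regression")
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  columns <- intersect(columns, names(cohort))
  has_na <- columns[vapply(columns, function(nm) anyNA(cohort[[nm]]),
                           logical(1))]
  for (nm in has_na) {
    frac <- mean(is.na(cohort[[nm]]))
    if (frac > 0.5)
      warning(sprintf("column '%s' is %.0f%% missing; imputations unstable",
                      nm, 100 * frac), call. = FALSE)
  }
  if (!length(has_na)) return(replicate(m, cohort, simplify = FALSE))

  if (is.null(predictors)) {
    cand <- c("age", "gender", "race", "diabetes", "dyslipidemia",
              "energy", "mma", "cvd")
    predictors <- cand[cand %in% names(cohort) &
                         !vapply(cand, function(nm)
                           nm %in% names(cohort) && anyNA(cohort[[nm]]),
                           logical(1))]
  }
  with_seed(seed, {
    lapply(seq_len(m), function(i)
      impute_once(cohort, has_na, predictors, cycles))
  })
}

# one chained-equation pass producing a single completed dataset
impute_once <- function(cohort, targets, predictors, cycles) {
  out <- cohort
  miss <- lapply(targets, function(nm) which(is.na(cohort[[nm]])))
  names(miss) <- targets
  # initialize by sampling observed values
  for (nm in targets) {
    obs <- out[[nm]][!is.na(out[[nm]])]
    out[[nm]][miss[[nm]]] <- sample(obs, length(miss[[nm]]), replace = TRUE)
  }
  for (cyc in seq_len(cycles)) {
    for (nm in targets) {
      idx <- miss[[nm]]
      rhs <- c(predictors, setdiff(targets, nm))
      obs_rows <- setdiff(seq_len(nrow(out)), idx)
      f <- stats::reformulate(rhs, response = nm)
      if (is.numeric(cohort[[nm]])) {
        fit <- stats::lm(f, data = out[obs_rows, , drop = FALSE])
        X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                 out[idx, , drop = FALSE])
        res <- stats::residuals(fit)
        df <- fit$df.residual
        sigma2 <- sum(res^2) / stats::rchisq(1, df)
        XtXinv <- chol2inv(qr.R(fit$qr))
        beta <- coef(fit) +
          drop(t(chol(sigma2 * XtXinv)) %*% stats::rnorm(length(coef(fit))))
        out[[nm]][idx] <- drop(X %*% beta) +
          stats::rnorm(length(idx), 0, sqrt(sigma2))
      } else {
        fit <- suppressMessages(
          nnet::multinom(f, data = out[obs_rows, , drop = FALSE],
                         trace = FALSE))
        pr <- stats::predict(fit, newdata = out[idx, , drop = FALSE],
                             type = "probs")
        if (is.null(dim(pr))) pr <- rbind(pr)
        lev <- levels(factor(cohort[[nm]]))
        if (ncol(pr) == 1L) pr <- cbind(1 - pr, pr)
        draw <- apply(pr, 1, function(p)
          sample(colnames(pr), 1L, prob = p))
        out[[nm]][idx] <- factor(draw, levels = lev)
      }
    }
  }
  out
}

#' Pool fits across imputed datasets by Rubin's rules
#'
#' Combines `m` fits with identical term sets: the pooled coefficient is
#' the mean of the per-imputation coefficients, the pooled covariance is
#' the mean within-imputation covariance plus `(1 + 1/m)` times the
#' between-imputation covariance, and per-term degrees of freedom follow
#' the classical Rubin formula
#' `(m - 1) * (1 + Wbar / ((1 + 1/m) B))^2`.
#'
#' @param fits list of fitted models supporting `coef()` and `vcov()`
#'   (e.g. [svy_logit()] fits).
#' @return An object of class `rubin_pooled` with `coefficients`, `vcov`,
#'   `m`, `within`, `between`, and `df`; `coef()`, `vcov()` and
#'   [odds_ratios()] work on it.
#' @export
rubin_pool <- function(fits) {
  m <- length(fits)
  if (m < 1L) stop("need at least one fit")
  terms_ref <- names(coef(fits[[1]]))
  for (f in fits)
    if (!identical(names(coef(f)), terms_ref))
      stop("term sets differ across fits", call. = FALSE)
  Q <- vapply(fits, coef, numeric(length(terms_ref)))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1,
                                   dimnames = list(terms_ref, NULL))
  qbar <- rowMeans(Q)
  W <- Reduce(`+`, lapply(fits, vcov)) / m
  B <- if (m == 1L) matrix(0, length(qbar), length(qbar))
       else tcrossprod(Q - qbar) / (m - 1)
  TT <- W + (1 + 1 / m) * B
  dimnames(TT) <- dimnames(W)
  bdiag <- diag(B)
  df <- if (m == 1L) rep(Inf, length(qbar))
        else ifelse(bdiag > 0,
                    (m - 1) * (1 + diag(W) / ((1 + 1 / m) * bdiag))^2,
                    Inf)
  structure(list(coefficients = qbar, vcov = TT, m = m,
                 within = W, between = B,
                 df = stats::setNames(df, terms_ref)),
            class = "rubin_pooled")
}

#' @export
coef.rubin_pooled <- function(object, ...) object$coefficients

#' @export
vcov.rubin_pooled <- function(object, ...) object$vcov

#' @export
print.rubin_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimates across %d imputations\n", x$m))
  se <- sqrt(diag(x$vcov))
  print(cbind(Estimate = x$coefficients, `Std. Error` = se, df = x$df))
  invisible(x)
}
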