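#' Design-based weighted mean and standard error
#'
#' Computes the Hajek estimator `sum(w * x) / sum(w)` and its standard
#' error by Taylor linearization over the design's (stratum, PSU)
#' clusters.  With equal weights the mean equals the arithmetic mean
#' exactly and the SE reduces to the classical `sd(x)/sqrt(n)`.
#'
#' @param values numeric vector, aligned with the design's rows; missing
#'   values are dropped together with their design rows.
#' @param design a [svy_design()] object.
#' @param single_psu see [svy_logit()].
#' @return Named numeric vector `c(mean, se)`.
#' @export
weighted_mean_se <- function(values, design,
                             single_psu = c("fail", "center")) {
  stopifnot(inherits(design, "svy_design"))
  single_psu <- match.arg(single_psu)
  if (length(values) != nrow(design$data))
    stop("values must align with the design rows", call. = FALSE)
  keep <- !is.na(values)
  if (!any(keep)) stop("all values are missing", call. = FALSE)
  x <- values[keep]
  w <- design$weights[keep]
  W <- sum(w)
  m <- sum(w * x) / W
  # influence contributions of the ratio estimator
  u <- w * (x - m) / W
  V <- taylor_linearized_vcov(matrix(u, ncol = 1), design$strata[keep],
                              design$psu[keep], single_psu = single_psu)
  c(mean = m, se = sqrt(drop(V)))
}

# design-based z-test for a difference of weighted means across a binary
# group (domain estimation); used by the descriptive table
svy_mean_diff_test <- function(values, group, design,
                               single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  res <- lapply(levels(g), function(lv) {
    idx <- !is.na(g) & g == lv & !is.na(values)
    weighted_mean_se(values[idx], subset_design(design, idx),
                     single_psu = single_psu)
  })
  diff <- res[[1]]["mean"] - res[[2]]["mean"]
  se <- sqrt(res[[1]]["se"]^2 + res[[2]]["se"]^2)
  z <- unname(diff / se)
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)),
       means = vapply(res, `[`, numeric(1), "mean"),
       ses = vapply(res, `[`, numeric(1), "se"))
}

#' Rao-Scott design-adjusted chi-square test
#'
#' First-order Rao-Scott correction of the Pearson chi-square test of
#' independence for weighted data: the Pearson statistic computed on
#' weighted cell proportions is divided by the mean generalized design
#' effect, estimated as `tr(Vsrs^-1 Vdesign) / df` where `Vdesign` is the
#' Taylor-linearized covariance of the cell residuals and `Vsrs` the
#' multinomial covariance at the weighted estimates (both under the same
#' with-replacement scaling).  With equal weights and no clustering the
#' correction equals 1 and the statistic reduces exactly to the classical
#' Pearson chi-square.
#'
#' @param a,b categorical vectors (coerced to factors) aligned with the
#'   design rows.
#' @param design a [svy_design()] object.
#' @param single_psu see [svy_logit()].
#' @return List with `statistic` (design-adjusted chi-square), `df`, `p`,
#'   `pearson` (uncorrected weighted Pearson statistic), and `deff` (mean
#'   generalized design effect).
#' @export
rao_scott_chisq <- function(a, b, design,
                            single_psu = c("fail", "center")) {
  stopifnot(inherits(design, "svy_design"))
  single_psu <- match.arg(single_psu)
  keep <- !is.na(a) & !is.na(b)
  a <- droplevels(factor(a[keep]))
  b <- droplevels(factor(b[keep]))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both variables need at least two observed levels", call. = FALSE)
  w <- design$weights[keep]
  strata <- design$strata[keep]
  psu <- design$psu[keep]
  n <- length(w)
  R <- nlevels(a); C <- nlevels(b)
  W <- sum(w)

  # weighted cell proportions (R x C), margins
  I <- matrix(0, n, R * C)
  cell <- (as.integer(a) - 1L) * C + as.integer(b)
  I[cbind(seq_len(n), cell)] <- 1
  phat <- colSums(w * I) / W
  P <- matrix(phat, R, C, byrow = TRUE)
  pr <- rowSums(P); pc <- colSums(P)
  if (any(pr <= 0) || any(pc <= 0))
    stop("empty row or column margin", call. = FALSE)

  E <- outer(pr, pc)
  X2 <- n * sum((P - E)^2 / E)
  d <- (R - 1L) * (C - 1L)

  # residual vector over the free cells r_rc = p_rc - pr*pc, r<R, c<C
  # Jacobian wrt the full cell-proportion vector (C-major within row)
  J <- matrix(0, d, R * C)
  k <- 0L
  for (r in seq_len(R - 1L)) {
    for (cc in seq_len(C - 1L)) {
      k <- k + 1L
      for (aa in seq_len(R)) {
        for (bb in seq_len(C)) {
          col <- (aa - 1L) * C + bb
          J[k, col] <- (aa == r) * (bb == cc) -
            (aa == r) * pc[cc] - (bb == cc) * pr[r]
        }
      }
    }
  }

  # linearized covariance of the free-cell residuals under the design
  h <- (w / W) * sweep(I, 2, phat)     # influence of cell proportions
  G <- h %*% t(J)
  Vd <- taylor_linearized_vcov(G, strata, psu, single_psu = single_psu)
  # multinomial (SRS with-replacement) covariance at the weighted
  # estimates, same n/(n-1) scaling as the design estimator
  S0 <- (diag(phat) - tcrossprod(phat)) / (n - 1)
  Vs <- J %*% S0 %*% t(J)
  # eigen pseudo-inverse guards the degenerate case (e.g. perfect
  # association) where the residual variance collapses; there the
  # correction is skipped and the Pearson statistic stands
  eg <- eigen(Vs, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  deff <- if (!any(pos)) 1 else {
    Vsi <- eg$vectors[, pos, drop = FALSE] %*%
      (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    sum(diag(Vsi %*% Vd)) / d
  }
  if (!is.finite(deff) || deff <= 0) deff <- 1
  stat <- X2 / deff
  list(statistic = stat, df = d,
       p = stats::pchisq(stat, df = d, lower.tail = FALSE),
       pearson = X2, deff = deff)
}
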