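test_that("equal weights and no clustering reduce to the classical MLE", {
  d <- sim_logistic(1200, seed = 21)
  fit <- svy_logit(y ~ x, svy_design(d))
  ref <- stats::glm(y ~ x, binomial, d)
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-6)
  expect_true(fit$converged)
})

test_that("unweighted 2x2 exposure model reproduces the cross-product odds ratio", {
  # published cohort margins: 335 cases vs 1110 non-cases in the low-OBS
  # group, 477 vs 2215 in the high-OBS group
  counts <- expand.grid(exposed = c(1, 0), case = c(1, 0))
  counts$n <- c(335, 477, 1110, 2215)
  rows <- counts[rep(seq_len(4), counts$n), c("exposed", "case")]
  fit <- svy_logit(case ~ exposed, svy_design(rows))
  or_hat <- exp(coef(fit)[["exposed"]])
  expect_equal(or_hat, (335 * 2215) / (477 * 1110), tolerance = 1e-8)
  expect_equal(round(or_hat, 3), 1.401)
})

test_that("the estimator is invariant to weight rescaling and row duplication", {
  d <- sim_logistic(400, seed = 22)
  d$w <- runif(400, 1, 5)
  d$st <- rep(1:4, each = 100)
  d$cl <- rep(1:20, each = 20)
  des <- svy_design(d, weights = "w", strata = "st", ids = "cl")
  fit <- svy_logit(y ~ x, des)

  d2 <- d; d2$w <- d$w * 1000
  fit2 <- svy_logit(y ~ x, svy_design(d2, "w", "st", "cl"))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
  expect_equal(vcov(fit2), vcov(fit), tolerance = 1e-8)
  rs <- rao_scott_chisq(d$y, d$x > 0, des)
  rs2 <- rao_scott_chisq(d2$y, d2$x > 0,
                         svy_design(d2, "w", "st", "cl"))
  expect_equal(rs2$statistic, rs$statistic, tolerance = 1e-10)

  # duplicating every row and halving weights leaves coefficients fixed
  d3 <- rbind(d, d); d3$w <- d3$w / 2
  fit3 <- svy_logit(y ~ x, svy_design(d3, weights = "w"))
  fit1 <- svy_logit(y ~ x, svy_design(d, weights = "w"))
  expect_equal(coef(fit3), coef(fit1), tolerance = 1e-8)
})

test_that("rank deficiency and degenerate outcomes raise informative errors", {
  d <- sim_logistic(200, seed = 23)
  d$x2 <- 2 * d$x
  expect_error(svy_logit(y ~ x + x2, svy_design(d)), "x2")
  d$y1 <- 1
  expect_error(svy_logit(y1 ~ x, svy_design(d)), "degenerate")
})

test_that("separation is flagged rather than silently reported", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = c(rep(0, 20), rep(1, 20)))
  expect_warning(fit <- svy_logit(y ~ x, svy_design(d)), "separation")
  expect_false(fit$converged)
  expect_warning(odds_ratios(fit), "non-converged")
})

test_that("odds ratios exponentiate coefficients with closed-form Wald limits", {
  d <- sim_logistic(600, seed = 24)
  fit <- svy_logit(y ~ x, svy_design(d))
  tab <- odds_ratios(fit)
  b <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  z975 <- stats::qnorm(0.975)
  expect_equal(tab$or, exp(b))
  expect_equal(tab$lower, exp(b - z975 * se))
  expect_equal(tab$upper, exp(b + z975 * se))
  expect_true(tab$lower <= tab$or && tab$or <= tab$upper)
  # coefficient 0 maps to OR 1 with a log-symmetric interval
  tab0 <- odds_ratios(structure(list(coefficients = c(a = 0),
                                     vcov = matrix(0.04, 1, 1,
                                                   dimnames = list("a", "a")),
                                     converged = TRUE),
                                class = "svy_logit"))
  expect_equal(tab0$or, 1)
  expect_equal(tab0$lower * tab0$upper, 1, tolerance = 1e-12)
  # identity on a published magnitude: coef log(1.53) -> OR 1.53
  expect_equal(exp(log(1.53)), 1.53)
})

test_that("weighted mean/SE match the arithmetic mean and a brute-force linearization", {
  d <- sim_logistic(300, seed = 25)
  des <- svy_design(d)
  wm <- weighted_mean_se(d$x, des)
  expect_identical(wm[["mean"]], sum(d$x) / 300)
  expect_equal(wm[["se"]], stats::sd(d$x) / sqrt(300))
  # constant vector has zero SE
  expect_equal(weighted_mean_se(rep(2.5, 300), des)[["se"]], 0)
  expect_error(weighted_mean_se(rep(NA_real_, 300), des), "missing")

  # clustered design against an independent direct implementation
  des2 <- toy_cluster_design(n_strata = 3, m = 6, seed = 26)
  d2 <- des2$data
  wm2 <- weighted_mean_se(d2$x, des2)
  W <- sum(d2$w)
  mu <- sum(d2$w * d2$x) / W
  u <- d2$w * (d2$x - mu) / W
  v <- 0
  for (h in unique(d2$stratum)) {
    zh <- tapply(u[d2$stratum == h], d2$psu[d2$stratum == h], sum)
    v <- v + length(zh) / (length(zh) - 1) * sum((zh - mean(zh))^2)
  }
  expect_equal(wm2[["mean"]], mu)
  expect_equal(wm2[["se"]], sqrt(v))
})

test_that("Taylor-linearized logistic vcov matches a brute-force sandwich on a toy design", {
  des <- toy_cluster_design(n_strata = 3, m = 10, seed = 27)
  d <- des$data
  fit <- svy_logit(y ~ x, des)
  # independent computation: bread from the weighted information,
  # meat from stratum-wise PSU score totals
  wn <- d$w / mean(d$w)
  X <- cbind(1, d$x)
  mu <- stats::plogis(drop(X %*% coef(fit)))
  A <- solve(t(X) %*% (wn * mu * (1 - mu) * X))
  sc <- X * (wn * (d$y - mu))
  meat <- matrix(0, 2, 2)
  for (h in unique(d$stratum)) {
    rows <- d$stratum == h
    zh <- rowsum(sc[rows, ], d$psu[rows])
    zc <- sweep(zh, 2, colMeans(zh))
    meat <- meat + nrow(zh) / (nrow(zh) - 1) * crossprod(zc)
  }
  expect_equal(unname(vcov(fit)), A %*% meat %*% A, tolerance = 1e-8)
})

test_that("single-PSU strata fail unless centering is requested", {
  d <- sim_logistic(60, seed = 28)
  d$st <- rep(1:3, each = 20)
  d$cl <- d$st                      # one PSU per stratum
  des <- svy_design(d, strata = "st", ids = "cl")
  expect_error(svy_logit(y ~ x, des), "single PSU")
  fit <- svy_logit(y ~ x, des, single_psu = "center")
  expect_true(all(is.finite(sqrt(diag(vcov(fit))))))
})

test_that("Rao-Scott statistic reduces to Pearson and detects association", {
  withr::local_seed(29)
  d <- data.frame(a = sample(letters[1:3], 700, replace = TRUE),
                  b = sample(LETTERS[1:2], 700, replace = TRUE))
  des <- svy_design(d)
  rs <- rao_scott_chisq(d$a, d$b, des)
  ref <- suppressWarnings(stats::chisq.test(table(d$a, d$b),
                                            correct = FALSE))
  expect_lt(abs(rs$statistic - unname(ref$statistic)), 1e-8)
  expect_equal(rs$deff, 1, tolerance = 1e-10)
  expect_equal(rs$df, 2L)

  # perfectly associated 2x2 has p near 0
  d2 <- data.frame(a = rep(0:1, each = 100), b = rep(0:1, each = 100))
  rs2 <- rao_scott_chisq(d2$a, d2$b, svy_design(d2))
  expect_lt(rs2$p, 1e-10)

  # empty margin errors
  expect_error(rao_scott_chisq(rep("a", 100), sample(0:1, 100, TRUE),
                               svy_design(data.frame(x = 1:100))),
               "two observed levels")
})

test_that("Rao-Scott matches a direct first-order oracle on a clustered toy design", {
  des <- toy_cluster_design(n_strata = 3, m = 12, seed = 30)
  d <- des$data
  rs <- rao_scott_chisq(d$g, d$y, des)
  # direct oracle: weighted Pearson over proportions, divided by the
  # trace-ratio design effect of the free-cell residual
  w <- d$w; W <- sum(w); n <- nrow(d)
  a <- factor(d$g); b <- factor(d$y)
  p11 <- sum(w[a == "a" & b == 0]) / W
  p12 <- sum(w[a == "a" & b == 1]) / W
  p21 <- sum(w[a == "b" & b == 0]) / W
  p22 <- sum(w[a == "b" & b == 1]) / W
  pr <- c(p11 + p12, p21 + p22); pc <- c(p11 + p21, p12 + p22)
  P <- matrix(c(p11, p12, p21, p22), 2, byrow = TRUE)
  X2 <- n * sum((P - outer(pr, pc))^2 / outer(pr, pc))
  # influence of the single free-cell residual r = p11 - pr1*pc1
  I11 <- as.numeric(a == "a" & b == 0)
  Ir <- as.numeric(a == "a"); Ic <- as.numeric(b == 0)
  h <- (w / W) * ((I11 - p11) - pc[1] * (Ir - pr[1]) -
                    pr[1] * (Ic - pc[1]))
  vd <- 0
  for (st in unique(d$stratum)) {
    rows <- d$stratum == st
    zh <- tapply(h[rows], d$psu[rows], sum)
    vd <- vd + length(zh) / (length(zh) - 1) * sum((zh - mean(zh))^2)
  }
  phat <- c(p11, p12, p21, p22)
  J <- c(1 - pc[1] - pr[1], -pc[1], -pr[1], 0)
  vs <- drop(t(J) %*% ((diag(phat) - tcrossprod(phat)) / (n - 1)) %*% J)
  expect_equal(rs$pearson, X2, tolerance = 1e-10)
  expect_equal(rs$deff, vd / vs, tolerance = 1e-8)
  expect_equal(rs$statistic, X2 / (vd / vs), tolerance = 1e-8)
})

test_that("Wald tests obey the normal-quantile identities", {
  fake <- structure(list(coefficients = c(`(Intercept)` = -1, t1 = 0,
                                          t2 = 1.959964 * 0.5),
                         vcov = diag(c(0.1, 0.04, 0.25)) |>
                           `dimnames<-`(list(c("(Intercept)", "t1", "t2"),
                                             c("(Intercept)", "t1", "t2"))),
                         converged = TRUE),
                    class = "svy_logit")
  expect_equal(wald_interaction_test(fake, "t1")$p, 1)
  expect_equal(wald_interaction_test(fake, "t2")$p, 0.05,
               tolerance = 1e-6)
  expect_error(wald_interaction_test(fake, "absent"), "absent")
  # joint test of one term equals the squared z test
  w1 <- wald_test(fake, "t2")
  expect_equal(w1$statistic, (1.959964 * 0.5)^2 / 0.25, tolerance = 1e-10)
})

test_that("the interaction z-test holds its type-I error under a null interaction", {
  withr::local_seed(31)
  n_rep <- 400
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 300
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, stats::plogis(-0.8 + 0.4 * x1 + 0.4 * x2))
    fit <- svy_logit(y ~ x1 * x2, svy_design(data.frame(x1, x2, y)))
    rej[r] <- wald_interaction_test(fit, "x1:x2")$p < 0.05
  }
  # binomial band around the nominal 5% level
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("predict, residuals and simulate are mutually consistent", {
  d <- sim_logistic(500, seed = 32)
  fit <- svy_logit(y ~ x, svy_design(d))
  pr <- predict(fit, newdata = d, type = "response")
  expect_equal(pr, fit$fitted, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(residuals(fit), d$y - fit$fitted)
  se <- predict(fit, newdata = d[1:5, ], type = "link", se.fit = TRUE)
  X <- cbind(1, d$x[1:5])
  expect_equal(se$se.fit, sqrt(diag(X %*% vcov(fit) %*% t(X))),
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_true(all(unlist(sims) %in% 0:1))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
})
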