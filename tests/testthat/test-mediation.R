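test_that("the null product interval is symmetric and contains zero", {
  ci <- distribution_of_product_ci(0, 1, 0, 1, draws = 2e5, seed = 51)
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
  # the product of two standard normals is symmetric about 0
  expect_lt(abs(ci[1] + ci[2]), 0.05)
  expect_equal(attr(ci, "estimate"), 0)
})

test_that("far from zero the interval converges to the Sobel interval", {
  ci <- distribution_of_product_ci(3, 0.1, 3, 0.1, draws = 1e6, seed = 52)
  sob <- attr(ci, "sobel")
  expect_lt(abs(ci[1] - sob[1]) / abs(sob[1]), 0.02)
  expect_lt(abs(ci[2] - sob[2]) / abs(sob[2]), 0.02)
})

test_that("Monte Carlo quantiles agree with a larger brute-force oracle", {
  # one off-grid case at module level (the acceptance suite sweeps a grid)
  a <- 0.4; se_a <- 0.15; b <- 0.25; se_b <- 0.1
  ci <- distribution_of_product_ci(a, se_a, b, se_b, draws = 1e6,
                                   seed = 53)
  withr::local_seed(54)
  oracle <- stats::quantile(stats::rnorm(5e6, a, se_a) *
                              stats::rnorm(5e6, b, se_b),
                            c(0.025, 0.975), names = FALSE)
  # MC error of a 97.5% quantile at 1e6 draws is ~1e-3 on this scale
  expect_lt(max(abs(as.numeric(ci) - oracle)), 5e-3)
})

test_that("seeded intervals are reproducible and inputs are validated", {
  a <- distribution_of_product_ci(0.2, 0.05, 0.3, 0.07, seed = 55,
                                  draws = 1e5)
  b <- distribution_of_product_ci(0.2, 0.05, 0.3, 0.07, seed = 55,
                                  draws = 1e5)
  expect_identical(a, b)
  expect_warning(distribution_of_product_ci(0.2, 0.05, 0.3, 0.07,
                                            draws = 100, seed = 1),
                 "noisy")
  expect_error(distribution_of_product_ci(Inf, 1, 0, 1), "non-finite")
  expect_error(distribution_of_product_ci(0, 0, 0, 1), "positive")
})

test_that("mediated proportion matches the published worked example and edge cases", {
  # printed subgroup row: product estimate 0.071 against total OR 1.61
  expect_equal(round(100 * mediated_proportion(0.071, log(1.61)), 1), 14.9)
  expect_equal(mediated_proportion(0, 0.3), 0)
  expect_equal(mediated_proportion(0.3, 0.3), 1)
  expect_error(mediated_proportion(0.1, 0), "zero")
  expect_warning(p <- mediated_proportion(-0.1, 0.5), "suppression")
  expect_true(attr(p, "inconsistent"))
})

test_that("null paths are estimated near zero with nominal uncertainty", {
  withr::local_seed(56)
  hits_a <- hits_b <- logical(30)
  for (r in seq_len(30)) {
    co <- add_groups(generate_cohort(truth_params(
      n = 2500, seed = 5600 + r, alpha_m = 0, beta_m = 0,
      mma_curvature = 0, missing_rates = numeric())))
    des <- svy_design(co, "weight", "stratum", "psu")
    paths <- estimate_paths("obs_group", "mma_group", "cvd",
                            c("age", "diabetes", "dyslipidemia"), des)
    hits_a[r] <- abs(paths$a[["est"]]) < 2 * paths$a[["se"]]
    hits_b[r] <- abs(paths$b[["est"]]) < 2 * paths$b[["se"]]
  }
  # ~95% coverage of zero; allow binomial slack at 30 replicates
  expect_gte(mean(hits_a), 0.8)
  expect_gte(mean(hits_b), 0.8)
})

test_that("injected paths are recovered within confidence limits at large n", {
  co <- add_groups(test_cohort(n = 20000, seed = 57))
  des <- svy_design(co, "weight", "stratum", "psu")
  paths <- estimate_paths("obs_group", "mma_group", "cvd",
                          c("age", "gender", "diabetes", "dyslipidemia"),
                          des)
  z <- stats::qnorm(0.975)
  expect_lt(abs(paths$a[["est"]] - log(1.32)), z * paths$a[["se"]])
  expect_lt(abs(paths$b[["est"]] - log(1.34)), z * paths$b[["se"]])
  expect_lt(abs(paths$c_prime[["est"]] - log(1.50)),
            z * paths$c_prime[["se"]])
})

test_that("run_mediation returns total-only or total-plus-levels structures", {
  co <- add_groups(test_cohort(n = 4000, seed = 58))
  des <- svy_design(co, "weight", "stratum", "psu")
  res1 <- run_mediation("obs_group", "mma_group", "cvd",
                        c("age", "gender"), des, draws = 5e4, seed = 59)
  expect_s3_class(res1, "mediation_result")
  expect_length(res1, 1L)
  expect_equal(res1[[1]]$label, "total")

  res3 <- run_mediation("obs_group", "mma_group", "cvd",
                        c("age", "gender"), des,
                        subgroups = "dyslipidemia", draws = 5e4, seed = 59)
  expect_length(res3, 3L)
  expect_equal(vapply(res3, `[[`, character(1), "label"),
               c("total", "dyslipidemia=0", "dyslipidemia=1"))
  tab <- as.data.frame(res3)
  expect_equal(nrow(tab), 3L)

  # exponential consistency: indirect OR and CI are exp of the product
  # scale quantities, exactly
  for (r in res3) {
    expect_identical(r$indirect_or, exp(r$ab))
    expect_identical(r$indirect_or_ci, exp(r$ab_ci))
    expect_identical(r$mediation_present, prod(r$ab_ci) > 0)
    expect_true(is.finite(r$decomposition_gap))
  }

  # determinism under a fixed seed
  res3b <- run_mediation("obs_group", "mma_group", "cvd",
                         c("age", "gender"), des,
                         subgroups = "dyslipidemia", draws = 5e4, seed = 59)
  expect_identical(as.data.frame(res3), as.data.frame(res3b))
})

test_that("degenerate subgroup levels are skipped with a message", {
  co <- add_groups(test_cohort(n = 3000, seed = 60))
  co$flag <- ifelse(seq_len(nrow(co)) <= 30, "tiny", "rest")
  co$cvd[co$flag == "tiny"] <- 0   # degenerate outcome in that level
  des <- svy_design(co, "weight", "stratum", "psu")
  expect_message(
    res <- run_mediation("obs_group", "mma_group", "cvd", character(),
                         des, subgroups = "flag", draws = 2e4, seed = 61),
    "skipped")
  expect_equal(vapply(res, `[[`, character(1), "label"),
               c("total", "flag=rest"))
})

test_that("mediation is localized to the stratum where it truly operates", {
  # mediation present only in the dyslipidemia stratum: build a compound
  # cohort where the non-dyslipidemia half has alpha_m = 0
  withr::local_seed(62)
  co_yes <- generate_cohort(truth_params(n = 10000, seed = 63,
                                         missing_rates = numeric()))
  co_no <- generate_cohort(truth_params(n = 10000, seed = 64,
                                        alpha_m = 0,
                                        missing_rates = numeric()))
  co_yes$dyslipidemia <- 1L
  co_no$dyslipidemia <- 0L
  co_no$id <- co_no$id + nrow(co_yes)
  co_no$stratum <- co_no$stratum + max(co_yes$stratum)
  co <- add_groups(rbind(co_yes, co_no))
  des <- svy_design(co, "weight", "stratum", "psu")
  res <- run_mediation("obs_group", "mma_group", "cvd",
                       c("age", "gender"), des,
                       subgroups = "dyslipidemia", draws = 1e5, seed = 65)
  labs <- vapply(res, `[[`, character(1), "label")
  yes <- res[[which(labs == "dyslipidemia=1")]]
  no <- res[[which(labs == "dyslipidemia=0")]]
  expect_true(yes$mediation_present)
  expect_false(no$mediation_present)
})

test_that("misaligned analytic samples are rejected unless aligned", {
  co <- add_groups(test_cohort(n = 2000, seed = 66))
  co$mma_group[1:50] <- NA
  des <- svy_design(co, "weight", "stratum", "psu")
  expect_error(estimate_paths("obs_group", "mma_group", "cvd",
                              character(), des, align_rows = FALSE),
               "align_rows")
  paths <- estimate_paths("obs_group", "mma_group", "cvd", character(),
                          des, align_rows = TRUE)
  expect_equal(paths$n, 1950L)
})
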