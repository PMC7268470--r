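test_that("pair joint distribution matches the closed form and sums to 1", {
  grid <- expand.grid(p = c(0.034, 0.1, 0.257, 0.5, 0.737),
                      rho = c(0, 0.011, 0.071, 0.3, 1))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; rho <- grid$rho[i]
    cells <- pair_joint_probs(p, rho)
    q <- p * (1 - p)
    expect_equal(unname(cells),
                 c(p^2 + q * rho, q * (1 - rho), q * (1 - rho),
                   (1 - p)^2 + q * rho))
    expect_equal(sum(cells), 1)
    # both margins equal p
    expect_equal(unname(cells["p11"] + cells["p10"]), p)
    expect_equal(unname(cells["p11"] + cells["p01"]), p)
  }
  expect_error(pair_joint_probs(0.05, -0.5), "infeasible")
})

test_that("correlated pairs have the prescribed margins and correlation", {
  # rho = 1: every pair identical
  pairs <- generate_correlated_pairs(500, p = 0.3, rho = 1, seed = 1)
  expect_identical(pairs$value_1, pairs$value_2)

  # rho = 0: members independent, present-present matches at chance p^2
  pairs <- generate_correlated_pairs(2e5, p = 0.3, rho = 0, seed = 2)
  p11 <- mean(pairs$value_1 == 1 & pairs$value_2 == 1)
  expect_equal(p11, 0.09, tolerance = 0.05)
  expect_lt(abs(phi_coefficient(pairs$value_1, pairs$value_2)), 0.01)

  # parameter recovery at smoking-like calibration, se(phi) ~ 1/sqrt(n)
  n <- 1e6
  pairs <- generate_correlated_pairs(n, p = 0.159, rho = 0.071, seed = 3)
  expect_equal(mean(pairs$value_1), 0.159, tolerance = 0.01)
  expect_lt(abs(phi_coefficient(pairs$value_1, pairs$value_2) - 0.071),
            0.002 * 2)
})

test_that("expected excess matches equal n p (1-p) rho", {
  # property: over feasible (p, rho), E[n11] - n p^2 = n p (1-p) rho
  for (i in 1:20) {
    p <- withr::with_seed(i, runif(1, 0.05, 0.95))
    rho <- withr::with_seed(i + 100, runif(1, 0, 0.5))
    cells <- pair_joint_probs(p, rho)
    n <- 1000
    expect_equal(n * unname(cells["p11"]) - n * p^2,
                 excess_matches(n, p, rho))
  }
})

test_that("donor pool generation honours strata, prevalence and missingness", {
  cfg <- tiny_config()
  spec <- data.frame(age_group = "35-39", gender = "male",
                     marital_status = "married", race = "white",
                     region = "A", year = 2005L, n = 1e5L,
                     prev_smoking = 0.159)
  donors <- generate_donor_pool(spec, "smoking", seed = 5)
  expect_identical(nrow(donors), 100000L)
  expect_equal(mean(donors$smoking), 0.159, tolerance = 0.004)
  expect_false(anyNA(donors$smoking))  # missing_rate = 0

  spec$prev_smoking <- 0
  donors0 <- generate_donor_pool(spec, "smoking", seed = 5)
  expect_true(all(donors0$smoking == 0L))

  spec$n <- -1L
  expect_error(generate_donor_pool(spec, "smoking", seed = 5), "negative")

  spec$n <- 1000L
  spec$prev_smoking <- 1.2
  expect_error(generate_donor_pool(spec, "smoking", seed = 5), "\\[0, 1\\]")
})

test_that("missingness is applied independently of the behaviour value", {
  spec <- data.frame(age_group = "35-39", gender = "male",
                     marital_status = "married", race = "white",
                     region = "A", year = 2005L, n = 4e4L,
                     prev_smoking = 0.5)
  donors <- generate_donor_pool(spec, "smoking", missing_rate = 0.2,
                                seed = 6)
  expect_equal(mean(is.na(donors$smoking)), 0.2, tolerance = 0.02)
  expect_equal(mean(donors$smoking, na.rm = TRUE), 0.5, tolerance = 0.02)
})

test_that("recipient cohorts match the strata spec exactly", {
  spec <- data.frame(age_group = c("40-44", "45-49"), gender = "male",
                     marital_status = "married", race = "white",
                     region = "A", year = 2010L, n = c(3L, 2L))
  rec <- generate_recipient_cohort(spec, seed = 1)
  expect_identical(nrow(rec), 5L)
  expect_identical(sum(rec$age_group == "40-44"), 3L)
  expect_true(all(is.na(rec$death_within_1yr)))
  expect_false(anyDuplicated(rec$id) > 0)

  empty <- generate_recipient_cohort(spec[spec$n < 0, ], seed = 1)
  expect_identical(nrow(empty), 0L)
})

test_that("survival simulation hits the death rate and target RR", {
  truth <- withr::with_seed(1, rbinom(27835, 1, 0.159))
  death <- simulate_survival(truth, target_rr = 2, death_rate = 0.54,
                             seed = 9)
  expect_lt(abs(mean(death) - 0.54), 0.01)  # > 3 s.e. at n = 27,835
  expect_equal(crude_rr(truth, death), 2, tolerance = 0.04)

  # null target: both groups share risk d
  death1 <- simulate_survival(truth, target_rr = 1, death_rate = 0.54,
                              seed = 10)
  expect_equal(crude_rr(truth, death1), 1, tolerance = 0.05)
})

test_that("the realized RR does not depend on the baseline death rate", {
  truth <- withr::with_seed(2, rbinom(5e4, 1, 0.25))
  rr <- vapply(c(0.2, 0.54, 0.7), function(d) {
    crude_rr(truth, simulate_survival(truth, 1.5, d, seed = 11))
  }, numeric(1))
  expect_true(all(abs(rr - 1.5) < 0.08))
})

test_that("infeasible targets error exactly at the feasibility boundary", {
  # low prevalence at RR = 2, d = 0.54: exposed risk 1.08/1.048 > 1
  truth <- rep(c(1L, 0L), c(48, 952))
  expect_error(simulate_survival(truth, 2, 0.54, seed = 1),
               class = "coldRR_not_possible")
  expect_false(feasible_target(2, 0.048, 0.54))
  expect_false(feasible_target(2, 0.034, 0.54))
  expect_true(feasible_target(2, 0.100, 0.54))

  # property: error iff target_rr * d / (1 + p (target_rr - 1)) > 1
  for (i in 1:50) {
    par <- withr::with_seed(i, c(runif(1, 0.01, 0.9), runif(1, 0.1, 0.9),
                                 runif(1, 0.3, 3)))
    p <- round(par[1], 2); d <- par[2]; rr <- par[3]
    truth <- rep(c(1L, 0L), round(c(p, 1 - p) * 100))
    p_emp <- mean(truth)
    should_fail <- rr * d / (1 + p_emp * (rr - 1)) > 1 ||
      d / (1 + p_emp * (rr - 1)) > 1
    got_error <- tryCatch({
      simulate_survival(truth, rr, d, seed = i)
      FALSE
    }, coldRR_not_possible = function(e) TRUE)
    expect_identical(got_error, should_fail)
  }
})
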