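test_that("per-behaviour donor datasets are complete-case and independent", {
  donors <- data.frame(id = paste0("D", 1:10), age_group = "35-39",
                       gender = "male", marital_status = "married",
                       race = "white", region = "A", year = 2005L,
                       a = c(NA, NA, rep(1L, 8)),
                       b = c(1L, 0L, NA, rep(0L, 7)))
  ds <- build_donor_datasets(donors, c("a", "b"))
  expect_identical(nrow(ds$a), 8L)
  expect_identical(nrow(ds$b), 9L)
  # D1 missing a but not b: absent from a's dataset, present in b's
  expect_false("D1" %in% ds$a$id)
  expect_true("D1" %in% ds$b$id)

  # no missingness: datasets identical to input
  full <- donors
  full$a <- 1L; full$b <- 0L
  ds2 <- build_donor_datasets(full, c("a", "b"))
  expect_identical(ds2$a, full)

  donors$a <- NA_integer_
  expect_error(build_donor_datasets(donors, c("a", "b")),
               "zero non-missing")
  expect_error(build_donor_datasets(donors, "zzz"), "zzz")
})

test_that("a recipient draws two distinct donors from its stratum", {
  cfg <- tiny_config()
  tabs <- one_stratum_tables(cfg, n_recipients = 1,
                             donor_values = c(1, 0, 1))
  cohort <- impute_double(tabs$recipients, tabs$donors, cfg, seed = 4)
  a <- cohort$assignments$smoking
  expect_identical(a$status, "served")
  expect_false(a$donor_id_1 == a$donor_id_2)
  expect_true(all(c(a$value_1, a$value_2) %in% 0:1))
})

test_that("donor exhaustion omits the recipient", {
  cfg <- tiny_config()
  tabs <- one_stratum_tables(cfg, n_recipients = 1, donor_values = 1)
  cohort <- impute_double(tabs$recipients, tabs$donors, cfg, seed = 4)
  a <- cohort$assignments$smoking
  expect_identical(a$status, "exhausted")
  expect_true(is.na(a$value_1) && is.na(a$value_2))
})

test_that("2 recipients with 5 donors consume 4 distinct donors", {
  cfg <- tiny_config()
  tabs <- one_stratum_tables(cfg, n_recipients = 2,
                             donor_values = c(1, 1, 0, 0, 1))
  for (seed in 1:20) {
    cohort <- impute_double(tabs$recipients, tabs$donors, cfg, seed = seed)
    a <- cohort$assignments$smoking
    expect_identical(a$status, c("served", "served"))
    used <- c(a$donor_id_1, a$donor_id_2)
    expect_identical(length(unique(used)), 4L)
  }
})

test_that("recipients with no matching stratum are counted separately", {
  cfg <- tiny_config()
  tabs <- one_stratum_tables(cfg, n_recipients = 2,
                             donor_values = c(1, 0, 1, 0))
  # second recipient asks for a year with no donors at all
  tabs$recipients$year[2] <- 2012L
  cohort <- impute_double(tabs$recipients, tabs$donors, cfg, seed = 1)
  expect_identical(cohort$assignments$smoking$status,
                   c("served", "no_stratum"))

  # youngest age group cannot shift down one group: unmatched
  tabs$recipients$age_group[1] <- cfg$age_groups[1]
  cohort2 <- impute_double(tabs$recipients, tabs$donors, cfg, seed = 1)
  expect_identical(cohort2$assignments$smoking$status[1], "no_stratum")

  rep <- imputation_report(cohort2)
  expect_identical(rep$no_stratum, 2L)
  expect_identical(rep$total, 2L + 0L)
})

test_that("imputed values come from the matched lag-shifted stratum", {
  cfg <- tiny_config()
  # two donor strata with deterministic behaviour: year-2005 donors all 1,
  # year-2007 donors all 0
  donors <- rbind(
    data.frame(id = paste0("A", 1:6), age_group = "35-39", gender = "male",
               marital_status = "married", race = "white", region = "A",
               year = 2005L, smoking = 1L),
    data.frame(id = paste0("B", 1:6), age_group = "35-39", gender = "male",
               marital_status = "married", race = "white", region = "A",
               year = 2007L, smoking = 0L))
  recipients <- data.frame(
    id = c("r1", "r2"), age_group = "40-44", gender = "male",
    marital_status = "married", race = "white", region = "A",
    year = c(2010L, 2012L), death_within_1yr = 0L)
  cohort <- impute_double(recipients, donors, cfg, seed = 8)
  a <- cohort$assignments$smoking
  expect_identical(a$value_1, c(1L, 0L))
  expect_identical(a$value_2, c(1L, 0L))
  expect_true(all(grepl("^A", c(a$donor_id_1[1], a$donor_id_2[1]))))
  expect_true(all(grepl("^B", c(a$donor_id_1[2], a$donor_id_2[2]))))
})

test_that("no donor serves twice within one behaviour and accounting conserves", {
  cfg <- tiny_config(c("smoking", "binge"))
  for (seed in 1:5) {
    donors <- make_donors(cfg, per_stratum = 5, seed = seed)
    recipients <- make_recipients(cfg, per_stratum = 3, seed = seed)
    cohort <- impute_double(recipients, donors, cfg, seed = seed)
    for (b in cfg$behaviours) {
      a <- cohort$assignments[[b]]
      used <- c(a$donor_id_1, a$donor_id_2)
      used <- used[!is.na(used)]
      expect_identical(anyDuplicated(used), 0L)
    }
    rep <- imputation_report(cohort)
    expect_true(all(rep$served + rep$exhausted + rep$no_stratum ==
                      nrow(recipients)))
  }
})

test_that("ample donor pools leave zero exclusions", {
  cfg <- tiny_config()
  donors <- make_donors(cfg, per_stratum = 10, seed = 2)
  recipients <- make_recipients(cfg, per_stratum = 5, seed = 2)  # 2x cover
  cohort <- impute_double(recipients, donors, cfg, seed = 3)
  rep <- imputation_report(cohort)
  expect_identical(rep$exhausted, 0L)
  expect_identical(rep$no_stratum, 0L)
  expect_identical(rep$served, nrow(recipients))
})

test_that("a starved pool excludes about the engineered fraction", {
  cfg <- tiny_config()
  # 10 recipients per stratum but only 2 donors: 1 served, 9 exhausted
  donors <- make_donors(cfg, per_stratum = 2, seed = 5)
  recipients <- make_recipients(cfg, per_stratum = 10, seed = 5)
  rep <- imputation_report(impute_double(recipients, donors, cfg, seed = 6))
  expect_equal(rep$exhausted / rep$total, 0.9, tolerance = 1e-9)
})

test_that("cold-deck marginal law: imputed frequency tracks donor prevalence", {
  cfg <- tiny_config()
  tabs <- one_stratum_tables(cfg, n_recipients = 1,
                             donor_values = rep(c(1, 0, 0, 0, 0), 8))
  hits <- vapply(1:400, function(r) {
    cohort <- impute_double(tabs$recipients, tabs$donors, cfg,
                            seed = derive_seed(123, "rep", r))
    cohort$assignments$smoking$value_1[1]
  }, integer(1))
  expect_lt(abs(mean(hits) - 0.2), 0.06)  # 3 binomial s.e.
})

test_that("imputation is deterministic in the seed", {
  cfg <- tiny_config()
  donors <- make_donors(cfg, per_stratum = 6, seed = 1)
  recipients <- make_recipients(cfg, per_stratum = 3, seed = 1)
  c1 <- impute_double(recipients, donors, cfg, seed = 77)
  c2 <- impute_double(recipients, donors, cfg, seed = 77)
  c3 <- impute_double(recipients, donors, cfg, seed = 78)
  expect_identical(c1$assignments, c2$assignments)
  expect_false(identical(c1$assignments, c3$assignments))
})
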