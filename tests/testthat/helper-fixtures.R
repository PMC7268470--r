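# Small programmatic fixtures shared across test files.

tiny_config <- function(behaviours = "smoking", ...) {
  study_config(behaviours = behaviours,
               age_groups = c("35-39", "40-44", "45-49", "50-54"),
               genders = c("male", "female"),
               marital_statuses = "married",
               races = "white",
               regions = "A",
               years = 2001:2014,
               ...)
}

# donors covering every stratum a recipient in `years` can ask for
make_donors <- function(config, per_stratum = 10, prevalence = 0.3,
                        seed = 1, years = 2001:2009) {
  grid <- expand.grid(age_group = config$age_groups,
                      gender = config$genders,
                      marital_status = config$marital_statuses,
                      race = config$races,
                      region = config$regions,
                      year = years,
                      stringsAsFactors = FALSE)
  grid$n <- as.integer(per_stratum)
  for (b in config$behaviours) grid[[paste0("prev_", b)]] <- prevalence
  generate_donor_pool(grid, config$behaviours, seed = seed)
}

make_recipients <- function(config, per_stratum = 2, seed = 1,
                            years = 2006:2014, death_rate = 0.5,
                            age_groups = config$age_groups[-1]) {
  grid <- expand.grid(age_group = age_groups,
                      gender = config$genders,
                      marital_status = config$marital_statuses,
                      race = config$races,
                      region = config$regions,
                      year = years,
                      stringsAsFactors = FALSE)
  grid$n <- as.integer(per_stratum)
  out <- generate_recipient_cohort(grid, seed = seed)
  out$death_within_1yr <- withr::with_seed(
    seed + 1000, stats::rbinom(nrow(out), 1L, death_rate))
  out
}

# single-stratum tables: m recipients, k donors, explicit behaviour values
one_stratum_tables <- function(config, n_recipients, donor_values) {
  recipients <- data.frame(
    id = paste0("R", seq_len(n_recipients)),
    age_group = "40-44", gender = "male", marital_status = "married",
    race = "white", region = "A", year = 2010L,
    death_within_1yr = rep(c(0L, 1L), length.out = n_recipients))
  donors <- data.frame(
    id = paste0("D", seq_along(donor_values)),
    age_group = "35-39", gender = "male", marital_status = "married",
    race = "white", region = "A", year = 2005L,
    smoking = as.integer(donor_values))
  list(recipients = recipients, donors = donors)
}
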