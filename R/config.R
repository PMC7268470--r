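#' Study configuration
#'
#' Collects every tunable of the imputation/estimation pipeline in one
#' validated object: the behaviour columns to impute, the category lists of
#' the six auxiliary variables that define imputation strata, the temporal
#' lag between donor survey year and recipient diagnosis year, the matching
#' age-group shift, and the repetition-engine settings.
#'
#' The defaults mirror the design of the motivating study: donors are taken
#' from records observed `lag_years = 5` calendar years before diagnosis and
#' one five-year age group younger (`age_group_shift = 1`), the algorithm is
#' repeated `repetitions = 100` times, summaries use the empirical 2.5/97.5
#' percentiles, and an imputation is labelled *failed* when more than
#' `failure_threshold = 0.05` of its corrected relative risks are impossible
#' (negative).
#'
#' @param behaviours character vector of binary behaviour column names
#'   expected in the donor table.
#' @param age_groups ordered character vector of age-group labels, youngest
#'   first (the age-group shift walks down this list).
#' @param genders,marital_statuses,races,regions category lists for the
#'   remaining auxiliary variables.
#' @param years integer vector of admissible recipient (diagnosis) years.
#' @param lag_years non-negative integer; donor survey year must equal
#'   recipient year minus this lag.
#' @param age_group_shift non-negative integer; donor age-group index must
#'   equal recipient age-group index minus this shift.
#' @param repetitions number of independent repetitions of the stochastic
#'   algorithm (>= 1).
#' @param seed master seed; every repetition derives an independent
#'   substream from it (see [derive_seed()]).
#' @param ci_percentiles length-2 increasing vector of percentile bounds for
#'   the empirical interval, on the 0-100 scale.
#' @param failure_threshold fraction in (0,1); imputation fails when the
#'   proportion of impossible corrected RRs exceeds it (strict `>`).
#' @param death_rate overall one-year death rate used by the survival
#'   simulator, in (0,1).
#' @param target_rrs positive target relative-risk grid for the simulation
#'   validation study.
#' @return an object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(behaviours = "smoking",
#'                     age_groups = c("35-39", "40-44"),
#'                     years = 2006:2014, repetitions = 10, seed = 1)
#' cfg$lag_years
#' @export
study_config <- function(behaviours,
                         age_groups = default_age_groups(),
                         genders = c("male", "female"),
                         marital_statuses = c("married", "single",
                                              "widowed", "divorced"),
                         races = c("white", "black", "api", "aian"),
                         regions = LETTERS[1:13],
                         years = 2006:2014,
                         lag_years = 5L,
                         age_group_shift = 1L,
                         repetitions = 100L,
                         seed = 1L,
                         ci_percentiles = c(2.5, 97.5),
                         failure_threshold = 0.05,
                         death_rate = 0.54,
                         target_rrs = default_target_grid()) {
  stopifnot(is.character(behaviours), length(behaviours) >= 1,
            !anyDuplicated(behaviours),
            is.character(age_groups), length(age_groups) >= 1,
            lag_years >= 0, age_group_shift >= 0,
            repetitions >= 1,
            length(ci_percentiles) == 2,
            ci_percentiles[1] < ci_percentiles[2],
            ci_percentiles[1] >= 0, ci_percentiles[2] <= 100,
            failure_threshold > 0, failure_threshold < 1,
            death_rate > 0, death_rate < 1,
            all(target_rrs > 0))
  structure(list(behaviours = behaviours,
                 age_groups = as.character(age_groups),
                 genders = as.character(genders),
                 marital_statuses = as.character(marital_statuses),
                 races = as.character(races),
                 regions = as.character(regions),
                 years = as.integer(years),
                 lag_years = as.integer(lag_years),
                 age_group_shift = as.integer(age_group_shift),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 ci_percentiles = as.numeric(ci_percentiles),
                 failure_threshold = failure_threshold,
                 death_rate = death_rate,
                 target_rrs = as.numeric(target_rrs)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  behaviours:      ", paste(x$behaviours, collapse = ", "), "\n")
  cat("  age groups:      ", length(x$age_groups), "ordered levels\n")
  cat("  years:           ", min(x$years), "-", max(x$years), "\n")
  cat("  donor matching:  year - ", x$lag_years,
      ", age group - ", x$age_group_shift, "\n", sep = "")
  cat("  repetitions:     ", x$repetitions, " (seed ", x$seed, ")\n", sep = "")
  cat("  failed rule:     > ", 100 * x$failure_threshold,
      "% impossible corrected RRs\n", sep = "")
  invisible(x)
}

#' Default five-year age-group labels
#'
#' Nine labels from 35-39 up to 75-79 plus an open 80+ group, youngest
#' first.
#' @return character vector of length 10.
#' @export
default_age_groups <- function() {
  c(paste(seq(35, 75, by = 5), seq(39, 79, by = 5), sep = "-"), "80+")
}

#' Default target relative-risk grid for the simulation study
#' @return numeric vector `c(0.50, 0.66, 0.80, 1.00, 1.25, 1.50, 2.00)`.
#' @export
default_target_grid <- function() c(0.50, 0.66, 0.80, 1.00, 1.25, 1.50, 2.00)

#' Read / write a study configuration as YAML
#'
#' A plain-text key-value snapshot of every [study_config()] field, so a run
#' is fully described by its config file plus the master seed.
#'
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  required <- c("behaviours", "age_groups")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
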