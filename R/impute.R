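#' Per-behaviour complete-case donor datasets
#'
#' Imputing a missing value into a missing value is avoided by building one
#' donor dataset per behaviour, each containing only the donors with a
#' non-missing value for that behaviour.  Behaviours are handled completely
#' independently: a donor missing behaviour A but not B is absent from A's
#' dataset and present in B's.
#'
#' @param donors donor table ([read_table()] donor schema).
#' @param behaviours character vector of behaviour column names.
#' @return named list mapping behaviour -> donor data.frame.
#' @export
build_donor_datasets <- function(donors, behaviours) {
  missing_cols <- setdiff(behaviours, names(donors))
  if (length(missing_cols)) {
    stop("donor table lacks behaviour column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- lapply(behaviours, function(b) {
    keep <- donors[!is.na(donors[[b]]), , drop = FALSE]
    if (nrow(keep) == 0) {
      stop("behaviour '", b, "' has zero non-missing donors")
    }
    keep
  })
  names(out) <- behaviours
  out
}

# stratum keys: donors are keyed on their own profile; recipients on the
# donor-side profile (age group one index down per shift, year minus lag).
# A recipient whose shifted age index falls off the youngest group gets NA.
donor_stratum_key <- function(x, config) {
  paste(match(x$age_group, config$age_groups), x$gender, x$marital_status,
        x$race, x$region, x$year, sep = "\r")
}

recipient_stratum_key <- function(x, config) {
  idx <- match(x$age_group, config$age_groups) - config$age_group_shift
  key <- paste(idx, x$gender, x$marital_status, x$race, x$region,
               x$year - config$lag_years, sep = "\r")
  key[is.na(idx) | idx < 1] <- NA_character_
  key
}

#' Double random cold-deck imputation
#'
#' For each behaviour independently, every recipient is matched to the
#' donor stratum sharing its auxiliary profile five years earlier and one
#' age group younger (lag and shift from the config), and two distinct
#' donor records are drawn uniformly at random *without replacement* within
#' the stratum — each donor serves at most one recipient per behaviour per
#' repetition.  Recipients are processed in a random order within each
#' stratum, so when donors run out the exclusion falls on an exchangeable
#' random subset rather than on input order.  A recipient is
#'
#' * `served` when two donors were available,
#' * `exhausted` when its stratum exists but ran out of donor pairs,
#' * `no_stratum` when no donor matches at all (including recipients whose
#'   shifted age index falls below the youngest group).
#'
#' @param recipients recipient table with complete auxiliary variables.
#' @param donor_datasets either a donor table (a per-behaviour complete-case
#'   split is built internally) or the output of [build_donor_datasets()].
#' @param config a [study_config()].
#' @param seed integer seed; each behaviour draws from its own derived
#'   substream.
#' @return an `imputed_cohort`: list with `assignments` (named list of
#'   data.frames `id`, `value_1`, `value_2`, `donor_id_1`, `donor_id_2`,
#'   `status`), `behaviours`, and `n_recipients`.
#' @export
impute_double <- function(recipients, donor_datasets, config, seed) {
  stopifnot(inherits(config, "study_config"))
  if (is.data.frame(donor_datasets)) {
    donor_datasets <- build_donor_datasets(donor_datasets, config$behaviours)
  }
  r_key <- recipient_stratum_key(recipients, config)

  assignments <- lapply(names(donor_datasets), function(b) {
    donors <- donor_datasets[[b]]
    d_key <- donor_stratum_key(donors, config)
    donor_pool <- split(seq_len(nrow(donors)), d_key)

    res <- data.frame(id = recipients$id,
                      value_1 = NA_integer_, value_2 = NA_integer_,
                      donor_id_1 = NA_character_,
                      donor_id_2 = NA_character_,
                      status = "no_stratum",
                      stringsAsFactors = FALSE)
    strata <- split(seq_len(nrow(recipients)), r_key)
    local_seed(derive_seed(seed, b, "impute"), {
      for (key in sort(names(strata))) {
        rows <- strata[[key]]
        pool <- donor_pool[[key]]
        if (is.null(pool)) next
        m <- length(rows)
        served <- min(m, length(pool) %/% 2L)
        rows <- rows[sample.int(m)]
        res$status[rows] <- "exhausted"
        if (served == 0) next
        take <- pool[sample.int(length(pool), 2L * served)]
        first <- take[seq_len(served)]
        second <- take[served + seq_len(served)]
        hit <- rows[seq_len(served)]
        res$value_1[hit] <- donors[[b]][first]
        res$value_2[hit] <- donors[[b]][second]
        res$donor_id_1[hit] <- donors$id[first]
        res$donor_id_2[hit] <- donors$id[second]
        res$status[hit] <- "served"
      }
    })
    res
  })
  names(assignments) <- names(donor_datasets)
  structure(list(assignments = assignments,
                 behaviours = names(donor_datasets),
                 n_recipients = nrow(recipients)),
            class = "imputed_cohort")
}

#' @export
print.imputed_cohort <- function(x, ...) {
  cat("<imputed_cohort> ", x$n_recipients, " recipients, ",
      length(x$behaviours), " behaviour(s)\n", sep = "")
  print(imputation_report(x))
  invisible(x)
}

#' Imputation accounting report
#'
#' Per-behaviour counts of recipients served, excluded because the donor
#' stratum was exhausted, and excluded because no donor stratum matched.
#' The three counts always sum to the number of input recipients.
#'
#' @param cohort an `imputed_cohort` from [impute_double()].
#' @return data.frame with columns `behaviour`, `served`, `exhausted`,
#'   `no_stratum`, `total`.
#' @export
imputation_report <- function(cohort) {
  stopifnot(inherits(cohort, "imputed_cohort"))
  rows <- lapply(cohort$behaviours, function(b) {
    st <- cohort$assignments[[b]]$status
    data.frame(behaviour = b,
               served = sum(st == "served"),
               exhausted = sum(st == "exhausted"),
               no_stratum = sum(st == "no_stratum"),
               total = length(st))
  })
  do.call(rbind, rows)
}

#' Served value pairs for one behaviour
#'
#' Convenience accessor returning the `value_1`/`value_2` pairs (and ids)
#' of recipients actually served for one behaviour.
#'
#' @param cohort an `imputed_cohort`.
#' @param behaviour behaviour name.
#' @return data.frame `id`, `value_1`, `value_2`.
#' @export
served_pairs <- function(cohort, behaviour) {
  stopifnot(inherits(cohort, "imputed_cohort"),
            behaviour %in% cohort$behaviours)
  a <- cohort$assignments[[behaviour]]
  a[a$status == "served", c("id", "value_1", "value_2")]
}
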