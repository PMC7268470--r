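#' Read a recipient or donor table
#'
#' Both tables are comma-separated UTF-8 text with a header row.  Shared
#' auxiliary columns: `id`, `age_group`, `gender`, `marital_status`, `race`,
#' `region`, `year`.  A recipient (registry-style) table additionally has
#' `death_within_1yr` (0/1, `year` is the diagnosis year) and an optional
#' `subgroup` column; a donor (survey-style) table has one 0/1 column per
#' behaviour declared in the config (`year` is the survey year).
#'
#' Header matching is case-insensitive.  Empty cells become `NA`.
#' Categorical values outside the config's declared category lists are set
#' to `NA` and a per-column count is reported via `message()`; such rows are
#' later excluded (and counted) by the pipeline, never silently dropped
#' here.
#'
#' @param path file path of the delimited table.
#' @param role `"recipient"` or `"donor"`.
#' @param config a [study_config()] declaring behaviours and category lists.
#' @return a `data.frame` with typed columns; attribute
#'   `"unparseable_counts"` records how many cells per column were
#'   invalidated during parsing.
#' @export
read_table <- function(path, role = c("recipient", "donor"), config) {
  role <- match.arg(role)
  stopifnot(inherits(config, "study_config"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character",
                    check.names = FALSE, na.strings = ""),
    error = function(e) stop("empty or unreadable table: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (nrow(raw) == 0 && ncol(raw) <= 1) stop("empty table: ", path)
  names(raw) <- tolower(names(raw))

  aux <- c("id", "age_group", "gender", "marital_status", "race",
           "region", "year")
  required <- switch(role,
                     recipient = c(aux, "death_within_1yr"),
                     donor = c(aux, config$behaviours))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) for role '", role, "': ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) stop("duplicate id values in ", path)

  counts <- integer(0)
  coerce_cat <- function(x, levels, col) {
    bad <- !is.na(x) & !(x %in% levels)
    counts[[col]] <<- sum(bad)
    x[bad] <- NA_character_
    x
  }
  out <- raw
  out$age_group <- coerce_cat(raw$age_group, config$age_groups, "age_group")
  out$gender <- coerce_cat(raw$gender, config$genders, "gender")
  out$marital_status <- coerce_cat(raw$marital_status,
                                   config$marital_statuses, "marital_status")
  out$race <- coerce_cat(raw$race, config$races, "race")
  out$region <- coerce_cat(raw$region, config$regions, "region")
  yr <- suppressWarnings(as.integer(raw$year))
  bad_yr <- !is.na(raw$year) & (is.na(yr) | !(yr %in% config$years))
  counts[["year"]] <- sum(bad_yr)
  yr[bad_yr] <- NA_integer_
  out$year <- yr

  binary_cols <- switch(role,
                        recipient = "death_within_1yr",
                        donor = config$behaviours)
  for (col in binary_cols) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- !is.na(raw[[col]]) & (is.na(v) | !(v %in% c(0L, 1L)))
    counts[[col]] <- sum(bad)
    v[bad] <- NA_integer_
    out[[col]] <- v
  }
  if ("subgroup" %in% names(out)) out$subgroup <- as.character(out$subgroup)

  bad_total <- sum(counts)
  if (bad_total > 0) {
    message("read_table: ", bad_total, " unparseable cell(s) set to missing (",
            paste(sprintf("%s: %d", names(counts)[counts > 0],
                          counts[counts > 0]), collapse = ", "), ")")
  }
  attr(out, "unparseable_counts") <- counts
  out
}

#' Write a recipient or donor table
#'
#' Inverse of [read_table()]: comma-separated, header row, missing values as
#' empty cells.  `read_table(write_table(x))` round-trips complete tables
#' losslessly.
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

# columns of the flat results table, in output order
results_columns <- c("behaviour", "subgroup", "target_rr", "estimand",
                     "median", "lower", "upper",
                     "impossible_count", "invalid_count", "failed")

# estimands whose summary cells are masked by the sentinel when the
# imputation failed (corrected true-RR scale only)
corrected_estimands <- c("rr_t", "adj_rr_t", "corrected_rr")

#' Write study results
#'
#' Writes the flat summary table (one row per behaviour x subgroup x
#' estimand, plus a `target_rr` column for simulation studies) and, when
#' draws are supplied, a machine-readable sidecar
#' `<path-sans-ext>_draws.csv` holding every per-repetition value.
#'
#' Rows of corrected estimands whose imputation tripped the failed rule
#' carry the sentinel token `"failed"` in the median/lower/upper cells;
#' targets that were infeasible for the survival simulator carry
#' `"not possible"`.  Numeric cells are written with full (17 significant
#' digit) precision so a write/read round trip is exact.
#'
#' @param summaries a `repetition_summary` data.frame as produced by
#'   [run_study()] or [run_simulation_study()].
#' @param path output file path for the summary table.
#' @param draws optional data.frame of per-repetition values.
#' @return `path`, invisibly.
#' @export
write_results <- function(summaries, path, draws = NULL) {
  out <- as.data.frame(summaries)
  for (col in setdiff(results_columns, names(out))) {
    out[[col]] <- rep(NA, nrow(out))
  }
  out <- out[results_columns]
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  for (col in c("median", "lower", "upper")) {
    cell <- fmt(out[[col]])
    masked <- !is.na(out$failed) & out$failed &
      out$estimand %in% corrected_estimands
    cell[masked] <- "failed"
    if ("feasible" %in% names(summaries)) {
      cell[!summaries$feasible] <- "not possible"
    }
    out[[col]] <- cell
  }
  out$target_rr <- fmt(out$target_rr)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(draws)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), "_draws.csv")
    num <- vapply(draws, is.numeric, logical(1)) &
      !vapply(draws, is.integer, logical(1))
    draws[num] <- lapply(draws[num], function(x) {
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    })
    utils::write.csv(draws, sidecar, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' Sentinel cells (`"failed"`, `"not possible"`) are returned as `NA` in the
#' numeric columns; the `failed` flag column preserves which rows were
#' masked.
#'
#' @param path file path.
#' @return data.frame with numeric `median`/`lower`/`upper`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  for (col in c("target_rr", "median", "lower", "upper")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  for (col in c("impossible_count", "invalid_count")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$failed <- as.logical(out$failed)
  out
}

#' Split a table into analysable and excluded rows
#'
#' A recipient is analysable only when every auxiliary variable and the
#' one-year death indicator are non-missing; a donor only needs complete
#' auxiliary variables (behaviour missingness is handled per behaviour by
#' [build_donor_datasets()]).  Exclusions are counted once, so
#' `nrow(kept) + excluded == nrow(x)`.
#'
#' @param x table from [read_table()].
#' @param role `"recipient"` or `"donor"`.
#' @return list with elements `kept` (data.frame), `excluded_missing`
#'   (integer count) and `excluded_ids`.
#' @export
complete_aux_cases <- function(x, role = c("recipient", "donor")) {
  role <- match.arg(role)
  aux <- c("age_group", "gender", "marital_status", "race", "region", "year")
  check <- if (role == "recipient") c(aux, "death_within_1yr") else aux
  ok <- stats::complete.cases(x[check])
  list(kept = x[ok, , drop = FALSE],
       excluded_missing = sum(!ok),
       excluded_ids = x$id[!ok])
}
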