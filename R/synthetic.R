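#' Joint distribution of a correlated binary pair
#'
#' The two imputed values assigned to one recipient are modelled as an
#' exchangeable binary pair with common prevalence `p` and phi correlation
#' `rho`.  The 2x2 joint is
#' \deqn{P_{11} = p^2 + p(1-p)\rho,\quad P_{10} = P_{01} = p(1-p)(1-\rho),
#'       \quad P_{00} = (1-p)^2 + p(1-p)\rho,}
#' so the expected count of behaviour-present matches in excess of the
#' chance level \eqn{np^2} is exactly \eqn{n\,p(1-p)\rho}.
#'
#' @param p prevalence in \[0, 1\].
#' @param rho phi correlation in \[-1, 1\].
#' @return named numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @export
pair_joint_probs <- function(p, rho) {
  stopifnot(p >= 0, p <= 1, rho >= -1, rho <= 1)
  q <- p * (1 - p)
  cells <- c(p11 = p^2 + q * rho,
             p10 = q * (1 - rho),
             p01 = q * (1 - rho),
             p00 = (1 - p)^2 + q * rho)
  bad <- names(cells)[cells < -1e-12 | cells > 1 + 1e-12]
  if (length(bad)) {
    stop("infeasible (p, rho): cell ", bad[1], " = ",
         signif(cells[bad[1]], 4), " outside [0, 1]")
  }
  pmin(pmax(cells, 0), 1)
}

#' Generate correlated binary pairs
#'
#' Draws `n` i.i.d. pairs from the [pair_joint_probs()] joint: both margins
#' have prevalence `p` and the empirical phi coefficient converges to
#' `rho`.  This is the fixture used to emulate double cold-deck imputation
#' at a known calibration.
#'
#' @param n number of pairs.
#' @param p prevalence.
#' @param rho phi correlation.
#' @param seed integer seed (substream; the caller's RNG state is
#'   untouched).
#' @return data.frame with integer columns `value_1`, `value_2`.
#' @examples
#' pairs <- generate_correlated_pairs(1000, p = 0.16, rho = 0.07, seed = 1)
#' colMeans(pairs)
#' @export
generate_correlated_pairs <- function(n, p, rho, seed) {
  stopifnot(n >= 0)
  probs <- pair_joint_probs(p, rho)
  cell <- local_seed(seed,
                     sample.int(4L, n, replace = TRUE, prob = probs))
  data.frame(value_1 = as.integer(cell %in% c(1L, 2L)),
             value_2 = as.integer(cell %in% c(1L, 3L)))
}

# expand a strata spec (data.frame of auxiliary columns + n, and for donors
# prevalence columns named after behaviours) into per-row records
expand_strata <- function(strata_spec) {
  stopifnot(is.data.frame(strata_spec), "n" %in% names(strata_spec))
  if (any(strata_spec$n < 0)) stop("negative stratum size")
  idx <- rep(seq_len(nrow(strata_spec)), strata_spec$n)
  strata_spec[idx, setdiff(names(strata_spec), "n"), drop = FALSE]
}

#' Generate a donor (survey-style) table
#'
#' Each row of `strata_spec` describes one stratum: the auxiliary columns
#' (`age_group`, `gender`, `marital_status`, `race`, `region`, `year`), a
#' stratum size `n`, and one prevalence column per behaviour named
#' `prev_<behaviour>`.  Behaviour values are independent Bernoulli draws at
#' the stratum prevalence; missingness (at rate `missing_rate`, per cell,
#' per behaviour) is applied independently of the value, emulating
#' item non-response.
#'
#' @param strata_spec data.frame as described above.
#' @param behaviours character vector of behaviour names.
#' @param missing_rate fraction of behaviour cells set missing.
#' @param seed integer seed.
#' @return donor table (data.frame) in the [read_table()] donor schema.
#' @export
generate_donor_pool <- function(strata_spec, behaviours, missing_rate = 0,
                                seed = 1L) {
  prev_cols <- paste0("prev_", behaviours)
  missing_prev <- setdiff(prev_cols, names(strata_spec))
  if (length(missing_prev)) {
    stop("strata_spec lacks prevalence column(s): ",
         paste(missing_prev, collapse = ", "))
  }
  prev <- strata_spec[prev_cols]
  if (any(unlist(prev) < 0 | unlist(prev) > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  out <- expand_strata(strata_spec)
  n <- nrow(out)
  local_seed(seed, {
    for (i in seq_along(behaviours)) {
      pr <- rep(strata_spec[[prev_cols[i]]], strata_spec$n)
      v <- stats::rbinom(n, 1L, pr)
      if (missing_rate > 0) {
        v[stats::runif(n) < missing_rate] <- NA_integer_
      }
      out[[behaviours[i]]] <- v
    }
  })
  out[prev_cols] <- NULL
  out <- cbind(id = paste0("D", seq_len(max(n, 0))), out)
  rownames(out) <- NULL
  out
}

#' Generate a recipient (registry-style) cohort
#'
#' Expands a strata spec (auxiliary columns plus `n`) into one row per case.
#' The one-year death indicator is left missing: outcomes come either from
#' real data or from [simulate_survival()].
#'
#' @param strata_spec data.frame of auxiliary columns plus stratum count
#'   `n`; an optional `subgroup` column is carried through.
#' @param seed integer seed (reserved; generation is deterministic).
#' @return recipient table in the [read_table()] recipient schema.
#' @export
generate_recipient_cohort <- function(strata_spec, seed = 1L) {
  out <- expand_strata(strata_spec)
  out$death_within_1yr <- rep(NA_integer_, nrow(out))
  out <- cbind(id = if (nrow(out)) paste0("R", seq_len(nrow(out)))
               else character(0),
               out)
  rownames(out) <- NULL
  out
}

#' Simulate one-year survival at a target relative risk
#'
#' Given a binary "true" behaviour vector, death indicators are drawn
#' independently with
#' \deqn{R_0 = d / (1 + \hat p\,(RR - 1)), \qquad R_1 = RR \cdot R_0,}
#' where \eqn{\hat p} is the *empirical* prevalence of the supplied truth
#' vector.  The expected overall death rate is then exactly `death_rate`
#' and the expected risk ratio between exposed and unexposed is exactly
#' `target_rr`, regardless of sampling noise in the truth vector.
#'
#' Low prevalence combined with a high death rate can push the exposed risk
#' past 1, in which case the target is unachievable and an error of class
#' `coldRR_not_possible` is signalled (the repetition engine records such
#' targets as "not possible" rather than aborting).
#'
#' @param truth integer 0/1 vector of true behaviour.
#' @param target_rr positive target risk ratio.
#' @param death_rate overall one-year death rate `d` in (0, 1).
#' @param seed integer seed.
#' @return integer 0/1 death vector of the same length as `truth`.
#' @export
simulate_survival <- function(truth, target_rr, death_rate, seed) {
  stopifnot(target_rr > 0, death_rate > 0, death_rate < 1,
            all(truth %in% c(0L, 1L)))
  p_hat <- mean(truth)
  r0 <- death_rate / (1 + p_hat * (target_rr - 1))
  r1 <- target_rr * r0
  if (r1 > 1 || r0 > 1) {
    stop(structure(class = c("coldRR_not_possible", "error", "condition"),
                   list(message = sprintf(
                     paste0("target RR %.3g not possible: exposed risk ",
                            "%.4g exceeds 1 (prevalence %.4g, death rate ",
                            "%.3g)"), target_rr, max(r1, r0), p_hat,
                     death_rate),
                     call = sys.call(-1))))
  }
  local_seed(seed,
             stats::rbinom(length(truth), 1L,
                           ifelse(truth == 1L, r1, r0)))
}

#' Is a target relative risk achievable by the survival simulator?
#'
#' @param target_rr positive target risk ratio.
#' @param p behaviour prevalence.
#' @param death_rate overall one-year death rate.
#' @return `TRUE` when the implied exposed and unexposed risks both lie in
#'   \[0, 1\].
#' @export
feasible_target <- function(target_rr, p, death_rate) {
  r0 <- death_rate / (1 + p * (target_rr - 1))
  r1 <- target_rr * r0
  r1 <= 1 && r0 <= 1
}

#' Reference calibration scenarios for the validation study
#'
#' The six health-behaviour scenarios (cohort size, prevalence and phi
#' correlation of the paired imputed values) used to exercise the
#' attenuation-correction estimator: current smoking, binge drinking,
#' heavy drinking, any physical activity, obesity, and current smoking
#' combined with regular drinking.  Prevalences span 0.034-0.737 and phi
#' 0.011-0.071, covering both the well-calibrated and the
#' information-starved regimes.
#'
#' @return data.frame with columns `behaviour`, `n`, `p`, `rho`.
#' @export
validation_scenarios <- function() {
  data.frame(
    behaviour = c("smoking", "binge_drinking", "heavy_drinking",
                  "physical_activity", "obese", "smoking_regular_drinking"),
    n = c(27835L, 27750L, 27749L, 27830L, 27796L, 27735L),
    p = c(0.159, 0.100, 0.048, 0.737, 0.257, 0.034),
    rho = c(0.071, 0.060, 0.011, 0.034, 0.030, 0.022))
}
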