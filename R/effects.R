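#' Crude relative risk from two binary vectors
#'
#' Cross-tabulates exposure against one-year death and returns
#' \eqn{RR = (a/n_1)/(b/n_0)} with `a`/`b` the exposed/unexposed deaths and
#' `n1`/`n0` the group sizes.
#'
#' @param exposure,death integer 0/1 vectors of equal length.
#' @return positive real, or `NA_real_` when the ratio is undefined (an
#'   empty exposure group or zero unexposed deaths); callers treat `NA` as
#'   an invalid repetition rather than an error.
#' @export
crude_rr <- function(exposure, death) {
  stopifnot(length(exposure) == length(death))
  ok <- !is.na(exposure) & !is.na(death)
  exposure <- exposure[ok]; death <- death[ok]
  n1 <- sum(exposure == 1); n0 <- sum(exposure == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  a <- sum(exposure == 1 & death == 1)
  b <- sum(exposure == 0 & death == 1)
  if (b == 0) return(NA_real_)
  (a / n1) / (b / n0)
}

#' Mantel-Haenszel pooled risk ratio across strata
#'
#' The Cochran-Mantel-Haenszel common risk ratio
#' \deqn{RR_{MH} = \frac{\sum_k a_k n_{0k} / N_k}
#'                      {\sum_k b_k n_{1k} / N_k},}
#' with \eqn{a_k}/\eqn{b_k} the exposed/unexposed deaths, \eqn{n_{1k}} /
#' \eqn{n_{0k}} the group sizes and \eqn{N_k} the size of stratum `k`
#' (here: age group, the confounder of one-year survival).  Strata with an
#' empty exposure group contribute zero to both sums; with a single
#' stratum the estimator collapses to [crude_rr()].
#'
#' @param exposure,death integer 0/1 vectors.
#' @param stratum stratum label per observation (e.g. age group).
#' @return positive real, or `NA_real_` when the denominator sum is zero.
#' @export
cmh_rr <- function(exposure, death, stratum) {
  stopifnot(length(exposure) == length(death),
            length(exposure) == length(stratum))
  ok <- !is.na(exposure) & !is.na(death) & !is.na(stratum)
  exposure <- exposure[ok]; death <- death[ok]; stratum <- stratum[ok]
  num <- 0; den <- 0
  for (rows in split(seq_along(exposure), stratum)) {
    e <- exposure[rows]; d <- death[rows]
    n1 <- sum(e == 1); n0 <- sum(e == 0); nk <- length(rows)
    if (n1 == 0 || n0 == 0) next
    a <- sum(e == 1 & d == 1)
    b <- sum(e == 0 & d == 1)
    num <- num + a * n0 / nk
    den <- den + b * n1 / nk
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Correct an imputed relative risk for misclassification
#'
#' Non-differential misclassification introduced by the imputation
#' attenuates the relative risk toward the null.  Assuming equal behaviour
#' prevalence between donors and cases within each stratum, the true
#' relative risk is recovered from the imputed one by
#' \deqn{RR_T = 1 - \frac{RR_i - 1}{(RR_i - 1)\,p\,(1-\rho) - \rho}.}
#' Extreme calibrations make this unstable: when the result is negative
#' (or non-finite, e.g. a zero denominator) it is an *impossible* value for
#' a relative risk and is flagged rather than thrown — the repetition
#' engine counts impossible draws and applies the failed rule.
#'
#' @param rr_i imputed relative risk (crude or age-adjusted).
#' @param p prevalence estimate \eqn{\hat p}.
#' @param rho phi estimate \eqn{\hat\rho}.
#' @return list with `value` (real, possibly negative/NaN) and `impossible`
#'   (logical).
#' @examples
#' correct_rr(1.064, p = 0.159, rho = 0.071)
#' correct_rr(1.05, p = 0.2, rho = 0)  # impossible: negative estimate
#' @export
correct_rr <- function(rr_i, p, rho) {
  if (is.na(rr_i) || is.na(p) || is.na(rho)) {
    return(list(value = NA_real_, impossible = NA))
  }
  denom <- (rr_i - 1) * p * (1 - rho) - rho
  value <- 1 - (rr_i - 1) / denom
  list(value = value, impossible = !is.finite(value) || value < 0)
}

#' Expected attenuation of a true relative risk under imputation
#'
#' The exact algebraic inverse of [correct_rr()]: the relative risk one
#' expects to observe on imputed exposure when the true relative risk is
#' `rr_t` and the imputation carries calibration `(p, rho)`,
#' \deqn{RR_i = 1 + \frac{(RR_T - 1)\,\rho}{1 + (RR_T - 1)\,p\,(1-\rho)}.}
#' Because \eqn{|\rho|} is small for cold-deck imputation, \eqn{RR_i} sits
#' close to 1 however far \eqn{RR_T} is from the null.
#'
#' @param rr_t true relative risk.
#' @param p prevalence.
#' @param rho phi correlation.
#' @return the attenuated (imputed-scale) relative risk.
#' @export
forward_attenuation <- function(rr_t, p, rho) {
  1 + (rr_t - 1) * rho / (1 + (rr_t - 1) * p * (1 - rho))
}
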