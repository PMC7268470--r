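#' Phi coefficient of two binary vectors
#'
#' The correlation coefficient for dichotomous variables,
#' \deqn{\varphi = \frac{n_{11} n_{00} - n_{10} n_{01}}
#'       {\sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}},}
#' identical to the Pearson correlation of the two 0/1 vectors.  Used here
#' to measure the agreement between the two imputed values per recipient
#' beyond what chance alone would produce.
#'
#' @param x,y integer 0/1 vectors of equal length (NAs dropped pairwise).
#' @return phi in \[-1, 1\], or `NA_real_` when a margin is degenerate (a
#'   row or column total of the 2x2 table is zero).
#' @examples
#' phi_coefficient(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0: independence
#' @export
phi_coefficient <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(all(x %in% c(0, 1)), all(y %in% c(0, 1)))
  n11 <- as.numeric(sum(x == 1 & y == 1))
  n10 <- as.numeric(sum(x == 1 & y == 0))
  n01 <- as.numeric(sum(x == 0 & y == 1))
  n00 <- as.numeric(sum(x == 0 & y == 0))
  denom <- sqrt(n11 + n10) * sqrt(n01 + n00) * sqrt(n11 + n01) *
    sqrt(n10 + n00)
  if (denom == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / denom
}

#' Excess behaviour-present matches beyond chance
#'
#' Under the excess-match model the expected number of behaviour-present to
#' behaviour-present agreements above the chance level \eqn{np^2} is
#' \eqn{n\,\hat p(1-\hat p)\hat\rho}: the information conveyed by the
#' imputation.
#'
#' @param n number of recipients with two imputed values.
#' @param p_hat prevalence estimate.
#' @param rho_hat phi estimate.
#' @return the excess-match count (real, may be negative if `rho_hat < 0`).
#' @export
excess_matches <- function(n, p_hat, rho_hat) {
  n * p_hat * (1 - p_hat) * rho_hat
}

#' Calibrate the imputation from the paired imputed values
#'
#' Estimates the prevalence \eqn{\hat p} by pooling both imputed vectors
#' (the proportion of 1s among all `2n` imputed values) and the correlation
#' \eqn{\hat\rho} as the phi coefficient between the pairs, then the excess
#' matches \eqn{n\hat p(1-\hat p)\hat\rho}.
#'
#' @param value_1,value_2 integer 0/1 vectors: the two imputed values per
#'   recipient.
#' @return object of class `calibration_result`: list with `n`, `p_hat`,
#'   `rho_hat`, `excess_matches`, and `valid` (`FALSE` when phi is
#'   undefined because a margin is degenerate).
#' @export
calibrate_pairs <- function(value_1, value_2) {
  ok <- !is.na(value_1) & !is.na(value_2)
  value_1 <- value_1[ok]; value_2 <- value_2[ok]
  n <- length(value_1)
  if (n == 0) stop("no served recipients to calibrate")
  p_hat <- (sum(value_1) + sum(value_2)) / (2 * n)
  rho_hat <- phi_coefficient(value_1, value_2)
  structure(list(n = n,
                 p_hat = p_hat,
                 rho_hat = rho_hat,
                 excess_matches = if (is.na(rho_hat)) NA_real_
                                  else excess_matches(n, p_hat, rho_hat),
                 valid = !is.na(rho_hat)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> n = ", x$n,
      ", p_hat = ", signif(x$p_hat, 4),
      ", rho_hat = ", signif(x$rho_hat, 4),
      ", excess matches = ", signif(x$excess_matches, 5),
      if (!x$valid) "  [degenerate margin]", "\n", sep = "")
  invisible(x)
}

#' Prevalence pooled over the two imputed vectors
#'
#' @param cohort an `imputed_cohort`.
#' @param behaviour behaviour name.
#' @return fraction of 1s among the `2n` imputed values of the served
#'   recipients.
#' @export
estimate_prevalence <- function(cohort, behaviour) {
  pairs <- served_pairs(cohort, behaviour)
  if (nrow(pairs) == 0) stop("no served recipients for '", behaviour, "'")
  (sum(pairs$value_1) + sum(pairs$value_2)) / (2 * nrow(pairs))
}
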