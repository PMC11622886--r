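#' Logistic growth trend
#'
#' The systematic trend used for total contraceptive prevalence and for the
#' modern share of use: a gradual rise at low prevalence, fastest growth
#' around the midpoint year, and a slowdown as the curve approaches its
#' asymptote.
#'
#' @param t year (vectorised).
#' @param asymptote upper plateau of the curve, in (0, 1].
#' @param rate growth rate per year; at `rate = 0` the curve is flat at
#'   half the asymptote.
#' @param midpoint year at which the curve reaches half its asymptote.
#' @return proportion(s) in (0, asymptote).
#' @export
#' @examples
#' logistic_trend(2005, 0.6, 0.1, 2005) # 0.3
logistic_trend <- function(t, asymptote, rate, midpoint) {
  assert_that(all(asymptote > 0 & asymptote <= 1),
              "asymptote must lie in (0, 1]")
  asymptote * invlogit(rate * (t - midpoint))
}

#' Unmet need as a function of total prevalence
#'
#' Unmet need for any method is modelled through the ratio of unmet need to
#' non-use: `unmet = (1 - cpr_total) * invlogit(alpha + beta * cpr_total)`.
#' A negative `beta` encodes the empirical pattern that, among non-users,
#' unmet need declines as overall contraceptive use rises.
#'
#' @param cpr_total total contraceptive prevalence, in \[0, 1\].
#' @param alpha intercept on the logit of the unmet/non-use ratio.
#' @param beta slope on `cpr_total`.
#' @return unmet need proportion in \[0, 1 - cpr_total\]; 0 at
#'   `cpr_total = 1`.
#' @export
#' @examples
#' unmet_relation(0.5, 0, -2) # 0.5 * invlogit(-1) = 0.1344707
unmet_relation <- function(cpr_total, alpha, beta) {
  assert_that(all(cpr_total >= 0 & cpr_total <= 1),
              "cpr_total must lie in [0, 1]")
  (1 - cpr_total) * invlogit(alpha + beta * cpr_total)
}

#' Stationary AR(1) distortion series
#'
#' Fluctuations around the systematic trends are modelled as a stationary
#' first-order autoregression on the logit scale. The first value is drawn
#' from the stationary distribution, variance `sigma^2 / (1 - rho^2)`, so
#' the whole series is stationary. With `sigma = 0` the series is
#' identically zero.
#'
#' @param rho autocorrelation, `|rho| < 1`.
#' @param sigma innovation standard deviation, `>= 0`.
#' @param years integer vector of consecutive years (only its length is
#'   used; the series is indexed by position).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of the same length as `years`.
#' @export
ar1_distortion <- function(rho, sigma, years, seed = NULL) {
  assert_that(abs(rho) < 1, "|rho| must be < 1")
  assert_that(sigma >= 0, "sigma must be non-negative")
  n <- length(years)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - rho^2))
  if (n > 1) {
    z <- stats::rnorm(n - 1, 0, sigma)
    for (i in 2:n) e[i] <- rho * e[i - 1] + z[i - 1]
  }
  e
}

# Stationary AR(1) covariance over an annual grid, optionally restricted to
# a subset of (possibly repeated) year positions.
ar1_cov <- function(rho, sigma, idx) {
  if (sigma == 0) return(matrix(0, length(idx), length(idx)))
  v <- sigma^2 / (1 - rho^2)
  v * rho^abs(outer(idx, idx, "-"))
}
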