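# Internal numerical helpers shared across modules.

logit <- function(p) log(p) - log1p(-p)

invlogit <- function(x) {
  # numerically stable on both tails
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fp_stop <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) fp_stop(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Posterior interval summary of a sample vector
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), so e.g. samples `1:100` give a median of
#' 50.5 and a 95% interval of (3.475, 97.525).
#'
#' @param x numeric vector of posterior draws.
#' @param probs probabilities; default the 2.5th, 50th and 97.5th percentiles.
#' @return named numeric vector `lower95`, `median`, `upper95` (for the
#'   default `probs`).
#' @keywords internal
#' @noRd
ci_quantiles <- function(x, probs = c(0.025, 0.5, 0.975)) {
  q <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
  names(q) <- c("lower95", "median", "upper95")[seq_along(probs)]
  q
}

#' Round a percentage the way the reports print it
#'
#' Half-even rounding to one decimal after conversion to percent, matching
#' the precision of published prevalence tables.
#'
#' @param p proportion (0-1 scale) or percentage if `scale = 1`.
#' @param scale multiplier applied before rounding (default 100).
#' @return numeric, percent to 1 decimal.
#' @export
#' @examples
#' percent1(0.37584) # 37.6
percent1 <- function(p, scale = 100) round(p * scale, 1)

# clamp observed proportions away from {0,1} before the logit transform;
# with an effective sample size, use the half-observation continuity rule
clamp_proportion <- function(p, n_eff = NULL) {
  lo <- if (!is.null(n_eff) && is.finite(n_eff)) 0.5 / n_eff else 1e-4
  pmin(pmax(p, lo), 1 - lo)
}
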