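# Derived indicators and target metrics, computed sample-wise on posterior
# trajectories and only then summarised (summaries of ratios, never ratios
# of summaries, because quantiles do not commute with the ratio identity).

#' Target specification for progress metrics
#'
#' Defaults encode the FP2020 benchmark of a 1.4 percentage-point annual
#' gain in mCPR over 2015-2020 and the SDG-era goal of at least 75% demand
#' satisfied with modern methods by 2030, with 2022 as the reference year
#' for user counts.
#'
#' @param ds_threshold demand-satisfied target, proportion in (0, 1].
#' @param ds_target_year year the target applies to.
#' @param mcpr_trend_benchmark benchmark annual mCPR gain, %p/year.
#' @param trend_window two years defining the change window.
#' @param reference_year_for_users baseline year for required-user counts.
#' @return list of class `fp_target_spec`.
#' @export
target_spec <- function(ds_threshold = 0.75, ds_target_year = 2030,
                        mcpr_trend_benchmark = 1.4,
                        trend_window = c(2015, 2020),
                        reference_year_for_users = 2022) {
  assert_that(ds_threshold > 0 && ds_threshold <= 1,
              "ds_threshold must lie in (0, 1]")
  assert_that(trend_window[1] < trend_window[2],
              "trend window start must precede its end")
  structure(as.list(environment()), class = "fp_target_spec")
}

#' Demand for family planning satisfied with modern methods
#'
#' The share of modern contraceptive use among women with a demand for
#' family planning: `mcpr / (mcpr + unmet_modern)`, defined as 0 when both
#' inputs are 0. Scale-free, so it applies equally to proportions and to
#' percentages.
#'
#' @param mcpr modern contraceptive prevalence.
#' @param unmet_modern unmet need for modern methods (same scale).
#' @return demand satisfied, same scale as the inputs' ratio (a proportion
#'   of demand).
#' @export
#' @examples
#' percent1(demand_satisfied(16.8, 27.9)) # 37.6% of demand satisfied
demand_satisfied <- function(mcpr, unmet_modern) {
  assert_that(all(mcpr >= 0) && all(unmet_modern >= 0),
              "inputs must be non-negative")
  d <- mcpr + unmet_modern
  ifelse(d > 0, mcpr / d, 0)
}

#' Unmet need for modern methods
#'
#' Women with unmet need under the any-method definition plus traditional
#' users (who are not using a modern method and therefore carry unmet need
#' for modern methods).
#'
#' @param unmet_any unmet need, any-method definition.
#' @param traditional traditional-method prevalence.
#' @param mcpr optional modern prevalence, used to validate that the three
#'   components cannot exceed 1.
#' @return unmet need for modern methods.
#' @export
unmet_modern <- function(unmet_any, traditional, mcpr = NULL) {
  assert_that(all(unmet_any >= 0 & unmet_any <= 1) &&
                all(traditional >= 0 & traditional <= 1),
              "inputs must lie in [0, 1]")
  if (!is.null(mcpr)) {
    assert_that(all(unmet_any + traditional + mcpr <= 1 + 1e-9),
                "unmet_any + traditional + mcpr exceeds 1")
  }
  unmet_any + traditional
}

#' Counts of women from a rate and a base population
#'
#' @param rate proportion in \[0, 1\].
#' @param mwra married women of reproductive age (count, >= 0).
#' @return expected count, `rate * mwra`.
#' @export
fp_counts <- function(rate, mwra) {
  assert_that(all(rate >= 0 & rate <= 1), "rate must lie in [0, 1]")
  assert_that(all(mwra >= 0), "mwra must be non-negative")
  rate * mwra
}

#' Annual change in mCPR over a window
#'
#' Per posterior draw, `100 * (mcpr(year1) - mcpr(year0)) / (year1 -
#' year0)` in percentage points per year, summarised as median and 95%
#' credible interval. Benchmark attainment is flagged both on the strict
#' credible-interval rule (lower bound at or above the benchmark) and on
#' the median alone.
#'
#' @param posterior an `fpem_fit`, `fp_posterior`, or sample array.
#' @param area area id.
#' @param window two grid years `(year0, year1)`, `year0 < year1`.
#' @param benchmark benchmark gain in %p/year (default 1.4).
#' @return list: `median`, `lower95`, `upper95` (in %p/year),
#'   `attained_cri`, `attained_median`, and the per-draw vector `draws`.
#' @export
annual_change <- function(posterior, area, window = c(2015, 2020),
                          benchmark = 1.4) {
  post <- as_posterior(posterior)
  assert_that(window[2] > window[1], "window must satisfy year1 > year0")
  yrs <- as.character(window)
  assert_that(all(yrs %in% dimnames(post)[[3]]),
              "window years must be on the grid")
  assert_that(area %in% dimnames(post)[[2]], "unknown area id")
  ch <- 100 * (post[, area, yrs[2], "mcpr"] - post[, area, yrs[1], "mcpr"]) /
    diff(window)
  q <- ci_quantiles(ch)
  list(median = unname(q["median"]), lower95 = unname(q["lower95"]),
       upper95 = unname(q["upper95"]),
       attained_cri = unname(q["lower95"]) >= benchmark,
       attained_median = unname(q["median"]) >= benchmark,
       draws = ch)
}

#' Probability of attaining the demand-satisfied target
#'
#' The percentage of posterior draws in which demand satisfied with modern
#' methods reaches at least the threshold in the target year. A probability
#' of exactly zero is rendered as the `".."` sentinel in formatted output
#' (see [format_table1()]).
#'
#' @param posterior an `fpem_fit`, `fp_posterior`, or sample array.
#' @param area area id.
#' @param spec a [target_spec()].
#' @return percentage in \[0, 100\], rounded to 1 decimal.
#' @export
attainment_probability <- function(posterior, area, spec = target_spec()) {
  post <- as_posterior(posterior)
  yr <- as.character(spec$ds_target_year)
  assert_that(yr %in% dimnames(post)[[3]], "target year must be on the grid")
  assert_that(area %in% dimnames(post)[[2]], "unknown area id")
  ds <- post[, area, yr, "ds_modern"]
  round(100 * mean(ds >= spec$ds_threshold), 1)
}

#' Required increase to reach the demand-satisfied target
#'
#' Per posterior draw: (i) in percentage points, the threshold share of
#' projected total demand in the target year minus mCPR in the reference
#' year; (ii) in users, the threshold share of projected demand counts in
#' the target year minus modern users in the reference year. Negative
#' requirements (areas already past the target) are reported as computed.
#'
#' @param posterior an `fpem_fit`, `fp_posterior`, or sample array.
#' @param populations data frame `area_id`, `year`, `mwra`.
#' @param area area id.
#' @param spec a [target_spec()].
#' @return list with `pct` and `users` summaries (median, lower95,
#'   upper95) and the per-draw vectors.
#' @export
required_increase <- function(posterior, populations, area,
                              spec = target_spec()) {
  post <- as_posterior(posterior)
  y2 <- as.character(spec$ds_target_year)
  y1 <- as.character(spec$reference_year_for_users)
  assert_that(all(c(y1, y2) %in% dimnames(post)[[3]]),
              "reference and target years must be on the grid")
  mwra_at <- function(yr) {
    m <- populations$mwra[populations$area_id == area &
                            populations$year == as.integer(yr)]
    if (length(m) != 1 || is.na(m)) {
      fp_stop("population count missing for area %s, year %s", area, yr)
    }
    m
  }
  m1 <- mwra_at(y1); m2 <- mwra_at(y2)
  demand2 <- post[, area, y2, "demand_modern"]
  mcpr1 <- post[, area, y1, "mcpr"]
  pct <- 100 * (spec$ds_threshold * demand2 - mcpr1)
  users <- spec$ds_threshold * demand2 * m2 - mcpr1 * m1
  list(pct = as.list(ci_quantiles(pct)),
       users = as.list(ci_quantiles(users)),
       pct_draws = pct, users_draws = users)
}

#' Aggregation-consistency diagnostic
#'
#' Compares, year by year, the population-weighted mean of subnational
#' posterior medians with the national posterior medians, using a paired
#' two-sided t-test across years. Years whose absolute gap exceeds
#' `gap_threshold` are flagged. Because the subnational and national models
#' are fitted separately, small discrepancies are expected; the test asks
#' whether they are systematic.
#'
#' @param posterior_sub posterior for the subnational units (divisions or
#'   regions); all areas present in it are aggregated.
#' @param posterior_nat posterior for the national series; its first area
#'   is used.
#' @param populations data frame `area_id`, `year`, `mwra` covering every
#'   subnational area and year.
#' @param quantity quantity compared (default `"mcpr"`).
#' @param gap_threshold absolute gap (proportion scale) above which a year
#'   is flagged.
#' @return list of class `fp_consistency`: `per_year` data frame (weighted
#'   aggregate, national median, gap, flag), `t_statistic`, `p_value`,
#'   `mean_gap`.
#' @export
aggregate_consistency <- function(posterior_sub, posterior_nat, populations,
                                  quantity = "mcpr", gap_threshold = 0.02) {
  sub <- as_posterior(posterior_sub)
  nat <- as_posterior(posterior_nat)
  years <- dimnames(sub)[[3]]
  assert_that(identical(years, dimnames(nat)[[3]]),
              "subnational and national grids differ")
  areas <- dimnames(sub)[[2]]
  nat_area <- dimnames(nat)[[2]][1]

  agg <- numeric(length(years))
  natm <- numeric(length(years))
  for (j in seq_along(years)) {
    yr <- as.integer(years[j])
    w <- vapply(areas, function(a) {
      m <- populations$mwra[populations$area_id == a & populations$year == yr]
      if (length(m) != 1 || is.na(m)) {
        fp_stop("population count missing for area %s, year %d", a, yr)
      }
      as.numeric(m)
    }, numeric(1))
    w <- w / sum(w)
    med <- vapply(areas, function(a)
      stats::median(sub[, a, j, quantity]), numeric(1))
    agg[j] <- sum(w * med)
    natm[j] <- stats::median(nat[, nat_area, j, quantity])
  }
  gap <- agg - natm
  tt <- if (stats::sd(gap) < 1e-12) {
    # identical series: no evidence of a systematic gap
    list(statistic = c(t = 0), p.value = 1)
  } else {
    stats::t.test(gap)
  }
  per_year <- data.frame(year = as.integer(years), aggregate = agg,
                         national = natm, gap = gap,
                         flagged = abs(gap) > gap_threshold)
  structure(list(per_year = per_year,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, mean_gap = mean(gap),
                 quantity = quantity),
            class = "fp_consistency")
}

#' @export
print.fp_consistency <- function(x, ...) {
  cat(sprintf(
    "Aggregation consistency (%s): mean gap %.4f, t = %.2f, p = %.3f; %d/%d years flagged\n",
    x$quantity, x$mean_gap, x$t_statistic, x$p_value,
    sum(x$per_year$flagged), nrow(x$per_year)))
  invisible(x)
}

#' Attainment report for a set of areas
#'
#' Convenience wrapper assembling, per area, the annual-change summary,
#' target-attainment probability and required increases into one table.
#'
#' @param fit an [fpem_fit()] object (its stored populations are used).
#' @param areas area ids (default: all fitted areas).
#' @param spec a [target_spec()].
#' @return data frame, one row per area.
#' @export
attainment_report <- function(fit, areas = NULL, spec = target_spec()) {
  assert_that(inherits(fit, "fpem_fit"), "fit must be an fpem_fit")
  areas <- areas %||% dimnames(fit$posterior)[[2]]
  rows <- lapply(areas, function(a) {
    ac <- annual_change(fit, a, spec$trend_window,
                        spec$mcpr_trend_benchmark)
    ri <- if (!is.null(fit$populations)) {
      required_increase(fit, fit$populations, a, spec)
    } else NULL
    data.frame(
      area_id = a,
      attainment_probability = attainment_probability(fit, a, spec),
      annual_change_median = round(ac$median, 2),
      annual_change_lower95 = round(ac$lower95, 2),
      annual_change_upper95 = round(ac$upper95, 2),
      trend_attained_cri = ac$attained_cri,
      trend_attained_median = ac$attained_median,
      required_increase_pct = if (is.null(ri)) NA_real_ else
        round(ri$pct$median, 1),
      required_additional_users = if (is.null(ri)) NA_real_ else
        round(ri$users$median))
  })
  do.call(rbind, rows)
}
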