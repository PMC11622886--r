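# Coverage-disruption scenario engine: provision and utilization indices,
# annual reduction scenarios, a log-linear link from coverage to mCPR
# screened on predictor significance, and projected paths with cumulative
# deltas versus the baseline projection.

scenario_levels <- c(none = 0, small = 0.05, moderate = 0.10, large = 0.25)

#' The 4 x 4 grid of reduction scenarios
#'
#' Annual reduction rates for provision (`x`) and utilization (`y`),
#' labelled none (0%), small (5%), moderate (10%) and large (25%).
#'
#' @return data frame of 16 rows: `x`, `y`, `x_label`, `y_label`.
#' @export
scenario_grid <- function() {
  g <- expand.grid(x = unname(scenario_levels), y = unname(scenario_levels),
                   KEEP.OUT.ATTRS = FALSE)
  g$x_label <- names(scenario_levels)[match(g$x, scenario_levels)]
  g$y_label <- names(scenario_levels)[match(g$y, scenario_levels)]
  g
}

#' Provision index from services data
#'
#' The product of per-capita health workers, facilities and health budget
#' per region-year, optionally normalised to 1 in a base year within each
#' region (removing the arbitrary units of the components).
#'
#' @param services data frame `area_id`, `year`, `hrh`, `fh`, `hb`.
#' @param normalize_base optional base year for within-region normalisation.
#' @return data frame `area_id`, `year`, `provision`.
#' @export
provision_index <- function(services, normalize_base = NULL) {
  need <- c("area_id", "year", "hrh", "fh", "hb")
  assert_that(all(need %in% names(services)),
              "services must have columns %s", paste(need, collapse = ", "))
  assert_that(all(services$hrh > 0 & services$fh > 0 & services$hb > 0),
              "provision components must be strictly positive")
  out <- data.frame(area_id = services$area_id, year = services$year,
                    provision = services$hrh * services$fh * services$hb)
  if (!is.null(normalize_base)) {
    for (a in unique(out$area_id)) {
      base <- out$provision[out$area_id == a & out$year == normalize_base]
      assert_that(length(base) == 1, "base year missing for area %s", a)
      out$provision[out$area_id == a] <-
        out$provision[out$area_id == a] / base
    }
  }
  out
}

#' Utilization index from demand and affordability
#'
#' `demand * (1 - poverty_rate)` per region-year, where affordability is
#' one minus the poverty rate.
#'
#' @param demand data frame `area_id`, `year`, `demand` (proportion), e.g.
#'   posterior medians of `demand_modern` from a fit.
#' @param services data frame with `area_id`, `year`, `poverty_rate`.
#' @return data frame `area_id`, `year`, `utilization`.
#' @export
utilization_index <- function(demand, services) {
  assert_that(all(c("area_id", "year", "demand") %in% names(demand)),
              "demand must have columns area_id, year, demand")
  assert_that(all(demand$demand >= 0 & demand$demand <= 1),
              "demand must lie in [0, 1]")
  assert_that(all(services$poverty_rate >= 0 & services$poverty_rate <= 1),
              "poverty_rate must lie in [0, 1]")
  key <- paste(services$area_id, services$year)
  ix <- match(paste(demand$area_id, demand$year), key)
  assert_that(!anyNA(ix), "services rows missing for some demand rows")
  data.frame(area_id = demand$area_id, year = demand$year,
             utilization = demand$demand * (1 - services$poverty_rate[ix]))
}

#' Apply an annual compounding reduction to an index series
#'
#' Values at year `t >= start_year` are multiplied by
#' `(1 - rate)^(t - start_year)`; earlier values are unchanged. A 25%
#' annual reduction over 10 years therefore compounds to a multiplier of
#' `0.75^10 = 0.056314`.
#'
#' @param value numeric index series.
#' @param years corresponding years.
#' @param rate annual reduction in \[0, 1).
#' @param start_year first year the reduction applies.
#' @return reduced series.
#' @export
apply_reduction <- function(value, years, rate, start_year) {
  assert_that(rate >= 0 && rate < 1, "rate must lie in [0, 1)")
  assert_that(start_year %in% years, "start_year must be in the series")
  mult <- ifelse(years >= start_year, (1 - rate)^(years - start_year), 1)
  value * mult
}

#' Fit the coverage-to-mCPR link model
#'
#' Log-linear regression of the baseline mCPR projection on the provision
#' and utilization indices over the panel of regions and years:
#' `ln(mcpr) = a_region + b ln(provision) + c ln(utilization)`, with region
#' fixed effects when more than one region is present. The indicator is
#' retained for scenario projection only if both predictors are
#' significant at `alpha` (two-sided).
#'
#' @param indicator data frame `area_id`, `year`, `mcpr` (baseline
#'   projection, proportions in (0, 1)).
#' @param provision output of [provision_index()].
#' @param utilization output of [utilization_index()].
#' @param alpha significance level of the screen (default 0.05).
#' @param label indicator label carried through to outputs.
#' @return object of class `fp_link`: the `lm` fit, coefficients
#'   `b_provision` and `c_utilization`, their p-values, `retained`, and the
#'   aligned panel.
#' @export
fit_link <- function(indicator, provision, utilization, alpha = 0.05,
                     label = "mCPR") {
  assert_that(all(c("area_id", "year", "mcpr") %in% names(indicator)),
              "indicator must have columns area_id, year, mcpr")
  assert_that(all(indicator$mcpr > 0 & indicator$mcpr < 1),
              "baseline mcpr must lie strictly in (0, 1) for the log link")
  key_p <- paste(provision$area_id, provision$year)
  key_u <- paste(utilization$area_id, utilization$year)
  k <- paste(indicator$area_id, indicator$year)
  ip <- match(k, key_p); iu <- match(k, key_u)
  assert_that(!anyNA(ip) && !anyNA(iu),
              "provision/utilization panels do not cover the indicator panel")
  panel <- data.frame(area_id = indicator$area_id, year = indicator$year,
                      mcpr = indicator$mcpr,
                      provision = provision$provision[ip],
                      utilization = utilization$utilization[iu])
  assert_that(all(panel$provision > 0 & panel$utilization > 0),
              "indices must be positive for the log link")
  if (stats::sd(log(panel$provision)) < 1e-12 ||
      stats::sd(log(panel$utilization)) < 1e-12) {
    fp_stop("singular link fit: a predictor is constant over the panel")
  }
  multi <- length(unique(panel$area_id)) > 1
  fml <- if (multi) {
    log(mcpr) ~ factor(area_id) + log(provision) + log(utilization)
  } else {
    log(mcpr) ~ log(provision) + log(utilization)
  }
  fit <- stats::lm(fml, data = panel)
  sm <- summary(fit)$coefficients
  b <- sm["log(provision)", ]
  cc <- sm["log(utilization)", ]
  structure(list(lm = fit, label = label,
                 b_provision = unname(b["Estimate"]),
                 c_utilization = unname(cc["Estimate"]),
                 p_provision = unname(b["Pr(>|t|)"]),
                 p_utilization = unname(cc["Pr(>|t|)"]),
                 retained = unname(b["Pr(>|t|)"]) < alpha &&
                   unname(cc["Pr(>|t|)"]) < alpha,
                 alpha = alpha, panel = panel),
            class = "fp_link")
}

#' @export
print.fp_link <- function(x, ...) {
  cat(sprintf("Coverage link for %s: b(provision) = %.3f (p = %.3g), c(utilization) = %.3f (p = %.3g)\n",
              x$label, x$b_provision, x$p_provision, x$c_utilization,
              x$p_utilization))
  cat("Screening outcome:", if (x$retained) "retained" else "rejected",
      sprintf("(both p < %.2f required)\n", x$alpha))
  invisible(x)
}

#' Project mCPR under the full scenario grid
#'
#' For each region and each (x, y) pair of the 4 x 4 grid, reduces the
#' provision index by `(1 - x)^t` and the utilization index by
#' `(1 - y)^t` from the start year and predicts mCPR through the link each
#' year. The (0, 0) scenario reproduces the link's unreduced prediction
#' exactly. The underlying demand inside utilization keeps evolving per the
#' baseline projection; only the reduction factors compound.
#'
#' @param link a retained [fit_link()] object; a rejected link is refused
#'   since only indicators passing the significance screen are projected.
#' @param grid scenario grid (default [scenario_grid()]).
#' @param start_year first year reductions apply (default the panel's first
#'   year).
#' @return object of class `fp_scenarios`: data frame `area_id`, `x`, `y`,
#'   `x_label`, `y_label`, `year`, `mcpr`, plus the baseline prediction in
#'   attribute `"baseline"`.
#' @export
project_scenarios <- function(link, grid = scenario_grid(),
                              start_year = NULL) {
  assert_that(inherits(link, "fp_link"), "link must be an fp_link")
  if (!link$retained) {
    fp_stop("link model was rejected by the significance screen (p = %.3g, %.3g); only screened indicators are projected",
            link$p_provision, link$p_utilization)
  }
  panel <- link$panel
  start_year <- start_year %||% min(panel$year)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    p <- panel
    p$provision <- apply_reduction(p$provision, p$year, grid$x[i], start_year)
    p$utilization <- apply_reduction(p$utilization, p$year, grid$y[i],
                                     start_year)
    pred <- exp(stats::predict(link$lm, newdata = p))
    out[[i]] <- data.frame(area_id = p$area_id, x = grid$x[i], y = grid$y[i],
                           x_label = grid$x_label[i],
                           y_label = grid$y_label[i],
                           year = p$year, mcpr = pmin(pred, 1))
  }
  res <- do.call(rbind, out)
  baseline <- data.frame(area_id = panel$area_id, year = panel$year,
                         mcpr = exp(stats::predict(link$lm)))
  structure(res, baseline = baseline, start_year = start_year,
            class = c("fp_scenarios", "data.frame"))
}

#' @export
print.fp_scenarios <- function(x, ...) {
  cat("Scenario projections:", length(unique(x$area_id)), "region(s) x",
      nrow(unique(x[, c("x", "y")])), "scenarios,",
      min(x$year), "-", max(x$year), "\n")
  invisible(x)
}

#' Cumulative change versus the baseline projection
#'
#' Per region and scenario: the gap between the scenario's mCPR in the
#' final year and (i) the baseline (FPET-style) projection for that year
#' (`delta_vs_baseline`) and (ii) the level at the start year
#' (`delta_vs_start`, negative when the path drops below its starting
#' level).
#'
#' @param result an [project_scenarios()] object.
#' @param fpet_projection data frame `area_id`, `year`, `mcpr` giving the
#'   baseline projection; defaults to the link-model baseline stored in
#'   `result`.
#' @param final_year defaults to the last projected year.
#' @return data frame `area_id`, `x`, `y`, `x_label`, `y_label`,
#'   `mcpr_final`, `delta_vs_baseline`, `delta_vs_start`, `below_start`.
#' @export
cumulative_change <- function(result, fpet_projection = NULL,
                              final_year = NULL) {
  assert_that(inherits(result, "fp_scenarios"),
              "result must come from project_scenarios()")
  base <- fpet_projection %||% attr(result, "baseline")
  final_year <- final_year %||% max(result$year)
  start_year <- attr(result, "start_year")
  rows <- list()
  for (a in unique(result$area_id)) {
    b <- base$mcpr[base$area_id == a & base$year == final_year]
    assert_that(length(b) == 1,
                "baseline projection missing for area %s in %d", a, final_year)
    sub <- result[result$area_id == a & result$year == final_year, ]
    s0 <- result[result$area_id == a & result$year == start_year, ]
    key <- paste(s0$x, s0$y)
    start_val <- s0$mcpr[match(paste(sub$x, sub$y), key)]
    rows[[a]] <- data.frame(
      area_id = a, x = sub$x, y = sub$y,
      x_label = sub$x_label, y_label = sub$y_label,
      mcpr_final = sub$mcpr,
      delta_vs_baseline = sub$mcpr - b,
      delta_vs_start = sub$mcpr - start_val,
      below_start = sub$mcpr < start_val)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot scenario paths for one region
#'
#' Line chart of the projected mCPR path per provision-reduction level at a
#' fixed utilization-reduction level, with the baseline prediction dashed.
#'
#' @param x an [project_scenarios()] object.
#' @param area region id (default: first).
#' @param y_level utilization reduction level shown (default 0).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fp_scenarios <- function(x, area = NULL, y_level = 0, ...) {
  area <- area %||% x$area_id[1]
  sub <- x[x$area_id == area & x$y == y_level, ]
  base <- attr(x, "baseline")
  base <- base[base$area_id == area, ]
  cols <- c(none = "black", small = "goldenrod", moderate = "darkorange3",
            large = "firebrick")
  graphics::plot(range(sub$year), range(c(sub$mcpr, base$mcpr)),
                 type = "n", xlab = "Year", ylab = "mCPR", ...)
  graphics::lines(base$year, base$mcpr, lty = 2)
  for (lv in names(cols)) {
    s <- sub[sub$x_label == lv, ]
    graphics::lines(s$year, s$mcpr, col = cols[lv], lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                   legend = names(cols), title = "provision reduction")
  invisible(x)
}
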