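# S3 methods for fpem_fit objects and helpers shared with the indicator
# functions, which accept either a fit or a bare posterior array.

#' Construct a posterior trajectory object from a sample array
#'
#' Wraps a `sample x area x year x quantity` array (as produced by
#' [fpem_fit()], or constructed directly, e.g. for diagnostics on
#' engineered draws) after validating dimensions, dimension names and the
#' sample-wise accounting identities among the quantities that are present.
#'
#' @param samples 4-d numeric array with `dimnames` for areas (2), years
#'   (3) and quantities (4). Quantities must be a subset of
#'   `cpr_total, mcpr, traditional, unmet_any, unmet_modern, demand_modern,
#'   ds_modern`.
#' @return the array, classed `fp_posterior`.
#' @export
fp_posterior <- function(samples) {
  assert_that(is.array(samples) && length(dim(samples)) == 4,
              "samples must be a 4-d array (sample, area, year, quantity)")
  dn <- dimnames(samples)
  assert_that(!is.null(dn[[2]]) && !is.null(dn[[3]]) && !is.null(dn[[4]]),
              "areas, years and quantities must be named")
  assert_that(all(dn[[4]] %in% fp_quantities),
              "unknown quantity name(s): %s",
              paste(setdiff(dn[[4]], fp_quantities), collapse = ", "))
  q <- dn[[4]]
  tol <- 1e-8
  chk <- function(lhs, rhs, what) {
    assert_that(max(abs(lhs - rhs)) < tol,
                "sample-wise identity violated: %s", what)
  }
  if (all(c("cpr_total", "mcpr", "traditional") %in% q)) {
    chk(samples[, , , "traditional"],
        samples[, , , "cpr_total"] - samples[, , , "mcpr"],
        "traditional = cpr_total - mcpr")
  }
  if (all(c("unmet_modern", "unmet_any", "traditional") %in% q)) {
    chk(samples[, , , "unmet_modern"],
        samples[, , , "unmet_any"] + samples[, , , "traditional"],
        "unmet_modern = unmet_any + traditional")
  }
  if (all(c("demand_modern", "mcpr", "unmet_modern") %in% q)) {
    chk(samples[, , , "demand_modern"],
        samples[, , , "mcpr"] + samples[, , , "unmet_modern"],
        "demand_modern = mcpr + unmet_modern")
  }
  structure(samples, class = "fp_posterior")
}

as_posterior <- function(x) {
  if (inherits(x, "fpem_fit")) return(x$posterior)
  if (inherits(x, "fp_posterior")) return(unclass(x))
  if (is.array(x) && length(dim(x)) == 4) return(x)
  fp_stop("expected an fpem_fit, fp_posterior, or 4-d sample array")
}

#' Summarise posterior trajectories
#'
#' Median and 95% credible interval (the 2.5th, 50th and 97.5th posterior
#' percentiles, linear-interpolation quantiles) per area, year and
#' quantity.
#'
#' @param posterior an `fpem_fit`, `fp_posterior`, or 4-d sample array.
#' @param quantities quantity names to summarise (default: all present).
#' @param areas,years optional subsets.
#' @return data frame `area_id`, `year`, `quantity`, `median`, `lower95`,
#'   `upper95`.
#' @export
summarize_posterior <- function(posterior, quantities = NULL, areas = NULL,
                                years = NULL) {
  post <- as_posterior(posterior)
  dn <- dimnames(post)
  quantities <- quantities %||% dn[[4]]
  assert_that(all(quantities %in% dn[[4]]),
              "unknown quantity name(s): %s",
              paste(setdiff(quantities, dn[[4]]), collapse = ", "))
  areas <- areas %||% dn[[2]]
  years <- as.character(years %||% dn[[3]])
  assert_that(all(areas %in% dn[[2]]), "unknown area id(s)")
  assert_that(all(years %in% dn[[3]]), "year(s) outside the grid")
  assert_that(dim(post)[1] >= 1, "empty sample dimension")
  out <- expand.grid(area_id = areas, year = as.integer(years),
                     quantity = quantities, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  qs <- t(apply(out, 1, function(r) {
    ci_quantiles(post[, r[["area_id"]], as.character(r[["year"]]),
                      r[["quantity"]]])
  }))
  out$median <- qs[, "median"]
  out$lower95 <- qs[, "lower95"]
  out$upper95 <- qs[, "upper95"]
  out
}

#' @export
print.fpem_fit <- function(x, ...) {
  d <- dim(x$posterior)
  cat("Subnational family-planning model fit\n")
  cat(sprintf("  areas: %d   years: %s-%s   posterior draws: %d (%d chains)\n",
              d[2], dimnames(x$posterior)[[3]][1],
              dimnames(x$posterior)[[3]][d[3]], d[1], x$config$chains))
  mr <- suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))
  cat(sprintf("  max split R-hat: %.3f (threshold %.2f)\n", mr,
              x$config$rhat_threshold))
  if (length(x$no_data_areas)) {
    cat("  prior-driven areas (no data):",
        paste(x$no_data_areas, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summary method for fpem_fit
#'
#' @param object an [fpem_fit()] object.
#' @param quantities,areas,years passed to [summarize_posterior()].
#' @param ... unused.
#' @return data frame of medians and 95% credible bounds.
#' @export
summary.fpem_fit <- function(object, quantities = NULL, areas = NULL,
                             years = NULL, ...) {
  summarize_posterior(object, quantities, areas, years)
}

#' Posterior median parameter estimates
#'
#' @param object an [fpem_fit()] object.
#' @param ... unused.
#' @return list with `areas` (natural-scale curve parameters per area) and
#'   `global` (rho, innovation SDs, source variance inflation).
#' @export
coef.fpem_fit <- function(object, ...) {
  th <- object$param_draws$theta
  ids <- dimnames(th)[[3]]
  med <- apply(th, c(3, 4), stats::median)
  areas <- t(apply(med, 1, function(r)
    natural_from_theta(stats::setNames(r, theta_names))))
  rownames(areas) <- ids
  glob <- apply(object$param_draws$glob, 3, stats::median)
  list(areas = areas, global = glob)
}

#' Predict indicator trajectories from a fit
#'
#' @param object an [fpem_fit()] object.
#' @param areas,years,quantities optional subsets (defaults: everything).
#' @param type `"summary"` for medians and 95% intervals, `"samples"` for
#'   the raw posterior sub-array.
#' @param ... unused.
#' @return data frame (summary) or 4-d array (samples).
#' @export
predict.fpem_fit <- function(object, areas = NULL, years = NULL,
                             quantities = NULL,
                             type = c("summary", "samples"), ...) {
  type <- match.arg(type)
  if (type == "summary") {
    return(summarize_posterior(object, quantities, areas, years))
  }
  post <- object$posterior
  dn <- dimnames(post)
  post[, areas %||% dn[[2]], as.character(years %||% dn[[3]]),
       quantities %||% dn[[4]], drop = FALSE]
}

#' Plot estimated trajectories for one area
#'
#' Median line with a shaded 95% credible band, and the observed survey
#' proportions for the plotted quantity when available.
#'
#' @param x an [fpem_fit()] object.
#' @param area area id (default: the country node).
#' @param quantity one of the posterior quantities (default `"mcpr"`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the summary data frame that was plotted.
#' @export
plot.fpem_fit <- function(x, area = NULL, quantity = "mcpr", ...) {
  dn <- dimnames(x$posterior)
  area <- area %||% dn[[2]][1]
  s <- summarize_posterior(x, quantities = quantity, areas = area)
  yrs <- s$year
  graphics::plot(yrs, s$median, type = "n", ylim = c(0, max(s$upper95) * 1.05),
                 xlab = "Year", ylab = quantity, ...)
  graphics::polygon(c(yrs, rev(yrs)), c(s$lower95, rev(s$upper95)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(yrs, s$median, col = "steelblue4", lwd = 2)
  obs <- x$observations
  if (!is.null(obs) && quantity %in% names(obs)) {
    o <- obs[obs$area_id == area & !is.na(obs[[quantity]]), ]
    if (nrow(o)) graphics::points(o$year, o[[quantity]], pch = 19)
  }
  invisible(s)
}
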