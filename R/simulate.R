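# Synthetic-data generators: true indicator trajectories, DHS/MICS-style
# survey observations, MWRA populations, and regional services data. The
# generating process deliberately mirrors the estimation model's assumed
# process (logistic trends with logit-scale AR(1) distortions) so that
# parameter recovery and calibration are well-posed.

#' Generator hyperparameters
#'
#' Country-level curve parameters and dispersions for the synthetic truth.
#' Defaults describe a Cameroon-like setting: total prevalence rising from
#' a few percent in 1990 toward a 0.6 asymptote (about 21% by 2022), a
#' modern share rising from about 0.2 to 0.8 over the same period, and an
#' unmet/non-use ratio declining with total prevalence.
#'
#' @param cpr_asymptote,cpr_rate,cpr_midpoint logistic parameters of the
#'   country's total-prevalence trend.
#' @param mod_asymptote,mod_rate,mod_midpoint logistic parameters of the
#'   country's modern-share trend.
#' @param unmet_alpha,unmet_beta coefficients of [unmet_relation()].
#' @param rho,sigma_cpr,sigma_mod,sigma_unmet AR(1) distortion parameters
#'   (shared `rho`; per-process innovation SDs, logit scale).
#' @param sd_region,sd_division parent-to-child dispersion of the
#'   transformed parameter vector (logit asymptote, log rate, midpoint year
#'   for each curve, unmet intercept), length 7.
#' @param mics_sd_inflation multiplier on the sampling SD of MICS-source
#'   observations relative to DHS.
#' @return list of class `fp_hyperparams`.
#' @export
fp_hyperparams <- function(cpr_asymptote = 0.6, cpr_rate = 0.08,
                           cpr_midpoint = 2030,
                           mod_asymptote = 0.85, mod_rate = 0.12,
                           mod_midpoint = 2000,
                           unmet_alpha = -0.4, unmet_beta = -1,
                           rho = 0.8, sigma_cpr = 0.06, sigma_mod = 0.06,
                           sigma_unmet = 0.08,
                           sd_region = c(0.30, 0.15, 3.0, 0.30, 0.15, 3.0, 0.20),
                           sd_division = c(0.20, 0.10, 2.0, 0.20, 0.10, 2.0, 0.15),
                           mics_sd_inflation = 1.5) {
  assert_that(abs(rho) < 1, "|rho| must be < 1")
  assert_that(all(c(sigma_cpr, sigma_mod, sigma_unmet) >= 0),
              "sigmas must be non-negative")
  assert_that(length(sd_region) == 7 && length(sd_division) == 7,
              "dispersion vectors must have length 7")
  structure(as.list(environment()), class = "fp_hyperparams")
}

# transformed parameter vector for one area's curves
theta_names <- c("la_cpr", "lr_cpr", "mid_cpr",
                 "la_mod", "lr_mod", "mid_mod", "alpha_unmet")

theta_from_natural <- function(hp) {
  c(la_cpr = logit(hp$cpr_asymptote), lr_cpr = log(hp$cpr_rate),
    mid_cpr = hp$cpr_midpoint,
    la_mod = logit(hp$mod_asymptote), lr_mod = log(hp$mod_rate),
    mid_mod = hp$mod_midpoint, alpha_unmet = hp$unmet_alpha)
}

natural_from_theta <- function(theta) {
  c(cpr_asymptote = invlogit(theta[["la_cpr"]]),
    cpr_rate = exp(theta[["lr_cpr"]]),
    cpr_midpoint = theta[["mid_cpr"]],
    mod_asymptote = invlogit(theta[["la_mod"]]),
    mod_rate = exp(theta[["lr_mod"]]),
    mod_midpoint = theta[["mid_mod"]],
    alpha_unmet = theta[["alpha_unmet"]])
}

# deterministic + distorted components for one area given theta and eps
area_trajectory <- function(theta, years, beta, eps_c, eps_r, eps_u) {
  nat <- natural_from_theta(theta)
  Lc <- logistic_trend(years, nat[["cpr_asymptote"]], nat[["cpr_rate"]],
                       nat[["cpr_midpoint"]])
  Lr <- logistic_trend(years, nat[["mod_asymptote"]], nat[["mod_rate"]],
                       nat[["mod_midpoint"]])
  P <- invlogit(logit(Lc) + eps_c)
  R <- invlogit(logit(Lr) + eps_r)
  Z <- invlogit(nat[["alpha_unmet"]] + beta * Lc + eps_u)
  list(cpr_total = P, r_modern = R, mcpr = P * R,
       traditional = P * (1 - R), unmet_any = (1 - P) * Z,
       trend_cpr = Lc, trend_mod = Lr)
}

#' Simulate true indicator trajectories over a hierarchy
#'
#' Draws one transformed parameter vector per area (regions scattered
#' around the country values, divisions around their region) and one AR(1)
#' distortion series per area and process, then evaluates the prevalence
#' model on an annual grid. With all sigmas zero the trajectories equal the
#' deterministic logistic curves.
#'
#' @param hierarchy an [make_hierarchy()] object.
#' @param years integer vector of consecutive years (default 1990:2030).
#' @param hyperparams an [fp_hyperparams()] object.
#' @param seed integer seed.
#' @return object of class `fp_truth`: list with `hierarchy`, `years`,
#'   `params` (per-area transformed parameters), `hyperparams`, and
#'   matrices (area x year) `cpr_total`, `r_modern`, `mcpr`, `traditional`,
#'   `unmet_any`.
#' @export
simulate_true_trajectories <- function(hierarchy, years = 1990:2030,
                                       hyperparams = fp_hyperparams(),
                                       seed = 1) {
  validate_hierarchy(hierarchy)
  assert_that(length(years) >= 1 && !is.unsorted(years),
              "years must be a non-decreasing range")
  assert_that(years[length(years)] >= years[1], "degenerate year range")
  hp <- hyperparams
  set.seed(seed)
  h <- as.data.frame(hierarchy)
  ids <- h$area_id
  theta0 <- theta_from_natural(hp)

  params <- matrix(NA_real_, nrow = length(ids), ncol = 7,
                   dimnames = list(ids, theta_names))
  params[h$level == "country", ] <- theta0
  for (a in ids[h$level == "region"]) {
    params[a, ] <- stats::rnorm(7, theta0, hp$sd_region)
  }
  for (a in ids[h$level == "division"]) {
    params[a, ] <- stats::rnorm(7, params[parent_of(hierarchy, a), ],
                                hp$sd_division)
  }

  ny <- length(years)
  mats <- lapply(1:5, function(i) matrix(
    NA_real_, length(ids), ny, dimnames = list(ids, years)))
  names(mats) <- c("cpr_total", "r_modern", "mcpr", "traditional", "unmet_any")
  for (a in ids) {
    eps_c <- ar1_distortion(hp$rho, hp$sigma_cpr, years)
    eps_r <- ar1_distortion(hp$rho, hp$sigma_mod, years)
    eps_u <- ar1_distortion(hp$rho, hp$sigma_unmet, years)
    tr <- area_trajectory(params[a, ], years, hp$unmet_beta,
                          eps_c, eps_r, eps_u)
    for (q in names(mats)) mats[[q]][a, ] <- tr[[q]]
  }
  structure(c(list(hierarchy = hierarchy, years = years,
                   params = params, hyperparams = hp), mats),
            class = "fp_truth")
}

#' @export
print.fp_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$params), "areas,",
      length(x$years), "years (", min(x$years), "-", max(x$years), ")\n")
  invisible(x)
}

#' Survey design table
#'
#' One planned survey per area and year. Defaults mirror Cameroon's survey
#' record: DHS in 1991, 1998, 2004, 2011, 2018 and MICS in 2000, 2006,
#' 2014, with effective sample sizes shrinking down the hierarchy.
#'
#' @param hierarchy an [make_hierarchy()] object.
#' @param years survey years.
#' @param source_by_year named character vector mapping year to
#'   `"DHS"`/`"MICS"`; unnamed years default to DHS.
#' @param n_eff_by_level named numeric vector of effective sample sizes per
#'   hierarchy level.
#' @param components which indicator components each survey reports.
#' @return data frame with columns `area_id`, `year`, `source_type`,
#'   `n_eff`, `components` (comma-separated).
#' @export
fp_survey_design <- function(hierarchy,
                             years = c(1991, 1998, 2000, 2004, 2006, 2011,
                                       2014, 2018),
                             source_by_year = c(`2000` = "MICS",
                                                `2006` = "MICS",
                                                `2014` = "MICS"),
                             n_eff_by_level = c(country = 2000, region = 800,
                                                division = 250),
                             components = c("cpr_total", "mcpr",
                                            "traditional", "unmet_any")) {
  validate_hierarchy(hierarchy)
  h <- as.data.frame(hierarchy)
  src <- ifelse(as.character(years) %in% names(source_by_year),
                source_by_year[as.character(years)], "DHS")
  d <- expand.grid(area_id = h$area_id, year = years,
                   stringsAsFactors = FALSE)
  d$source_type <- src[match(d$year, years)]
  d$n_eff <- n_eff_by_level[h$level[match(d$area_id, h$area_id)]]
  d$components <- paste(components, collapse = ",")
  assert_that(all(d$n_eff >= 1), "effective sample sizes must be >= 1")
  d[order(d$area_id, d$year), , drop = FALSE]
}

#' Simulate survey observations around the truth
#'
#' For each design row, each reported component is drawn around its true
#' value with sampling standard deviation `sqrt(p (1 - p) / n_eff)`,
#' inflated by `mics_sd_inflation` for MICS-source rows. Components not in
#' the design's `components` list are emitted as `NA`. Infinite `n_eff`
#' (or zero truth variance) reproduces the truth exactly.
#'
#' @param truth an `fp_truth` object.
#' @param design a [fp_survey_design()] table.
#' @param seed integer seed.
#' @return data frame of observations: `area_id`, `year`, `source_type`,
#'   `n_eff`, `cpr_total`, `mcpr`, `traditional`, `unmet_any`.
#' @export
simulate_surveys <- function(truth, design, seed = 1) {
  assert_that(inherits(truth, "fp_truth"), "truth must be an fp_truth")
  assert_that(all(design$area_id %in% rownames(truth$params)),
              "design contains unknown area_id")
  assert_that(all(design$year %in% truth$years),
              "design contains years outside the truth grid")
  set.seed(seed)
  infl <- ifelse(design$source_type == "MICS",
                 truth$hyperparams$mics_sd_inflation, 1)
  comps <- c("cpr_total", "mcpr", "traditional", "unmet_any")
  out <- design[, c("area_id", "year", "source_type", "n_eff")]
  for (q in comps) out[[q]] <- NA_real_
  yix <- match(design$year, truth$years)
  for (i in seq_len(nrow(design))) {
    reported <- strsplit(design$components[i], ",", fixed = TRUE)[[1]]
    for (q in intersect(comps, reported)) {
      p <- truth[[q]][design$area_id[i], yix[i]]
      sdv <- if (is.finite(design$n_eff[i])) {
        sqrt(p * (1 - p) / design$n_eff[i]) * infl[i]
      } else 0
      out[[q]][i] <- min(max(stats::rnorm(1, p, sdv), 1e-6), 1 - 1e-6)
    }
  }
  rownames(out) <- NULL
  out
}

#' Population generator settings
#'
#' @param base_count married women of reproductive age (MWRA) in the whole
#'   country in the first grid year.
#' @param growth_rate annual exponential growth rate.
#' @param region_conc,division_conc Dirichlet concentration parameters for
#'   the population shares of regions within the country and of divisions
#'   within their region (larger = more even shares).
#' @return list of settings.
#' @export
fp_population_settings <- function(base_count = 2e6, growth_rate = 0.025,
                                   region_conc = 5, division_conc = 5) {
  list(base_count = base_count, growth_rate = growth_rate,
       region_conc = region_conc, division_conc = division_conc)
}

# integer apportionment preserving the total (largest remainder)
apportion <- function(total, shares) {
  raw <- total * shares / sum(shares)
  fl <- floor(raw)
  rem <- round(total - sum(fl))
  if (rem > 0) {
    extra <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  fl
}

#' Simulate MWRA population counts by area and year
#'
#' The country total grows log-linearly; region shares and division shares
#' within regions are fixed Dirichlet draws, and counts are apportioned so
#' division counts sum exactly to their region and regions to the country.
#'
#' @param hierarchy an [make_hierarchy()] object.
#' @param years integer year grid.
#' @param settings [fp_population_settings()].
#' @param seed integer seed.
#' @return data frame `area_id`, `year`, `mwra` (integer counts).
#' @export
simulate_population <- function(hierarchy, years = 1990:2030,
                                settings = fp_population_settings(),
                                seed = 1) {
  validate_hierarchy(hierarchy)
  set.seed(seed)
  h <- as.data.frame(hierarchy)
  regions <- h$area_id[h$level == "region"]
  rsh <- stats::rgamma(length(regions), settings$region_conc)
  rsh <- rsh / sum(rsh)
  dsh <- lapply(regions, function(r) {
    dv <- children_of(hierarchy, r)
    s <- stats::rgamma(length(dv), settings$division_conc)
    stats::setNames(s / sum(s), dv)
  })
  names(dsh) <- regions

  rows <- list()
  for (t in years) {
    total <- round(settings$base_count *
                     exp(settings$growth_rate * (t - years[1])))
    rcounts <- apportion(total, rsh)
    rows[[length(rows) + 1]] <- data.frame(
      area_id = "C", year = t, mwra = total)
    for (j in seq_along(regions)) {
      rows[[length(rows) + 1]] <- data.frame(
        area_id = regions[j], year = t, mwra = rcounts[j])
      dv <- dsh[[regions[j]]]
      dcounts <- apportion(rcounts[j], dv)
      rows[[length(rows) + 1]] <- data.frame(
        area_id = names(dv), year = t, mwra = dcounts)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$area_id <- as.character(out$area_id)
  assert_that(all(out$mwra >= 0), "counts must be non-negative")
  out
}

#' Services generator settings
#'
#' Means and variation of the regional provision components (health
#' workers, facilities, budget, all per capita) and the poverty rate.
#' Means are on arbitrary per-capita scales; the scenario module
#' normalises indices to a base year, so only relative variation matters.
#'
#' @param hrh_mean,fh_mean,hb_mean per-capita means.
#' @param trend annual log-scale drift common to the provision components.
#' @param sd_region log-scale SD of fixed regional effects.
#' @param sd_noise log-scale SD of year-to-year noise.
#' @param poverty_mean mean poverty rate (proportion).
#' @param poverty_sd logit-scale SD of regional poverty effects.
#' @return list of settings.
#' @export
fp_services_settings <- function(hrh_mean = 1e-3, fh_mean = 5e-5,
                                 hb_mean = 12, trend = 0.02,
                                 sd_region = 0.2, sd_noise = 0.03,
                                 poverty_mean = 0.375, poverty_sd = 0.3) {
  as.list(environment())
}

#' Simulate regional services data
#'
#' Per region-year: strictly positive per-capita health workers (HRH),
#' facilities (FH) and health budget (HB) following log-linear drift with
#' regional effects and noise, and a poverty rate in (0, 1). With
#' `sd_region = sd_noise = poverty_sd = 0` and `trend = 0` every row is
#' identical.
#'
#' @param regions character vector of region area ids.
#' @param years integer year grid.
#' @param settings [fp_services_settings()].
#' @param seed integer seed.
#' @return data frame `area_id`, `year`, `hrh`, `fh`, `hb`, `poverty_rate`.
#' @export
simulate_services <- function(regions, years,
                              settings = fp_services_settings(), seed = 1) {
  assert_that(length(regions) >= 1, "at least one region required")
  set.seed(seed)
  s <- settings
  eff <- matrix(stats::rnorm(length(regions) * 4, 0, s$sd_region),
                nrow = length(regions))
  pov_eff <- stats::rnorm(length(regions), 0, s$poverty_sd)
  rows <- list()
  for (j in seq_along(regions)) {
    dt <- years - years[1]
    mk <- function(mu, k) {
      mu * exp(eff[j, k] + s$trend * dt +
                 stats::rnorm(length(years), 0, s$sd_noise))
    }
    rows[[j]] <- data.frame(
      area_id = regions[j], year = years,
      hrh = mk(s$hrh_mean, 1), fh = mk(s$fh_mean, 2), hb = mk(s$hb_mean, 3),
      poverty_rate = invlogit(logit(s$poverty_mean) + pov_eff[j] +
                                stats::rnorm(length(years), 0, s$sd_noise)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  assert_that(all(out$hrh > 0 & out$fh > 0 & out$hb > 0),
              "provision components must be positive")
  out
}
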