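# Model-fit behaviour on small synthetic datasets. Fits here use reduced
# MCMC settings; convergence warnings are expected and suppressed since the
# assertions target structural properties, not chain diagnostics.

small_fit <- function(seed = 1, years = 2000:2030, sd_division = NULL,
                      obs_years = c(2004, 2011, 2014, 2018)) {
  h <- tiny_hierarchy()
  truth <- simulate_true_trajectories(h, years, seed = 100 + seed)
  des <- fp_survey_design(h, years = obs_years)
  obs <- simulate_surveys(truth, des, seed = 200 + seed)
  args <- list(years = years, chains = 2, warmup = 250, draws = 250,
               seed = seed)
  if (!is.null(sd_division)) args$sd_division <- sd_division
  cfg <- do.call(fpem_config, args)
  list(fit = quiet_fit(obs, h, NULL, cfg), truth = truth, obs = obs, h = h)
}

test_that("a fixed seed gives bitwise-identical summaries", {
  f1 <- small_fit(seed = 7)
  f2 <- small_fit(seed = 7)
  expect_identical(summary(f1$fit), summary(f2$fit))
  expect_identical(f1$fit$posterior, f2$fit$posterior)
})

test_that("posterior draws satisfy the accounting identities sample-wise", {
  f <- small_fit(seed = 3)
  post <- f$fit$posterior
  expect_true(all(post >= 0 & post <= 1))
  expect_s3_class(fp_posterior(post), "fp_posterior") # identity validation
  ds <- post[, , , "ds_modern"]
  dm <- post[, , , "demand_modern"]
  m <- post[, , , "mcpr"]
  expect_true(all(abs(ds * dm - m) < 1e-9))
})

test_that("projection intervals are wider than estimation intervals", {
  f <- small_fit(seed = 4)
  s <- summary(f$fit, quantities = "mcpr")
  for (a in unique(s$area_id)) {
    w <- function(yr) {
      r <- s[s$area_id == a & s$year == yr, ]
      r$upper95 - r$lower95
    }
    expect_gte(w(2030), w(2018))
  }
})

test_that("overwhelming exact data pins the posterior at the data value", {
  h <- tiny_hierarchy()
  yrs <- 2000:2030
  obs <- exact_surveys("R01", 2000:2019, cpr_total = 0.50, mcpr = 0.30,
                       unmet_any = 0.20, n_eff = 1e5)
  cfg <- fpem_config(years = yrs, chains = 2, warmup = 300, draws = 300,
                     seed = 11,
                     fix = list(rho = 0.5, kappa = 1))
  fit <- quiet_fit(obs, h, NULL, cfg)
  s <- summary(fit, quantities = "mcpr", areas = "R01",
               years = c(2005, 2012, 2019))
  expect_true(all(abs(s$median - 0.30) < 0.02))
})

test_that("widening division-level dispersion widens division intervals", {
  narrow <- small_fit(seed = 5,
                      sd_division = c(0.05, 0.05, 0.5, 0.05, 0.05, 0.5, 0.05))
  wide <- small_fit(seed = 5,
                    sd_division = c(0.60, 0.30, 6.0, 0.60, 0.30, 6.0, 0.45))
  dv <- area_ids(narrow$h, "division")
  wn <- summary(narrow$fit, quantities = "mcpr", areas = dv)
  ww <- summary(wide$fit, quantities = "mcpr", areas = dv)
  expect_gt(mean(ww$upper95 - ww$lower95), mean(wn$upper95 - wn$lower95) - 1e-3)
})

test_that("areas without data are flagged but still estimated", {
  h <- tiny_hierarchy()
  obs <- exact_surveys("R01", c(2005, 2015), cpr_total = 0.4, mcpr = 0.2,
                       unmet_any = 0.2, n_eff = 500)
  # reduced-MCMC convergence warnings are irrelevant to this check
  muffled <- function() {
    withCallingHandlers(
      fpem_fit(obs, h, NULL, quick_config(seed = 6)),
      warning = function(w) {
        if (grepl("convergence", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  expect_warning(quiet2 <- muffled(), "without observations")
  s <- summary(quiet2, quantities = "mcpr", areas = area_ids(h, "division"))
  expect_true(all(is.finite(s$median)))
})

test_that("malformed observations are rejected with pointed messages", {
  h <- tiny_hierarchy()
  cfg <- quick_config(seed = 2)
  base <- exact_surveys("R01", 2010, 0.4, 0.2, 0.2, n_eff = 500)

  bad_area <- base; bad_area$area_id <- "ghost"
  expect_error(fpem_fit(bad_area, h, NULL, cfg), "missing from the hierarchy")

  bad_p <- base; bad_p$cpr_total <- 1.4
  expect_error(fpem_fit(bad_p, h, NULL, cfg), "outside \\[0, 1\\]")

  orphan_m <- data.frame(area_id = "R01", year = 2010, source_type = "DHS",
                         n_eff = 500, mcpr = 0.2)
  expect_error(fpem_fit(orphan_m, h, NULL, cfg), "modern share")

  bad_src <- base; bad_src$source_type <- "CENSUS"
  expect_error(fpem_fit(bad_src, h, NULL, cfg), "DHS or MICS")
})
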