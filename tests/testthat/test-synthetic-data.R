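test_that("zero-noise trajectories reproduce the deterministic curves", {
  h <- tiny_hierarchy()
  hp <- flat_hyperparams(cpr_asymptote = 0.6, cpr_rate = 0.1,
                         cpr_midpoint = 2005)
  tr <- simulate_true_trajectories(h, 1990:2030, hp, seed = 1)
  # logistic at its midpoint is half the asymptote, for every area
  expect_equal(unname(tr$cpr_total[, "2005"]), rep(0.3, nrow(tr$params)))
  # the whole curve matches the closed form
  expect_equal(unname(tr$cpr_total["C", ]),
               logistic_trend(1990:2030, 0.6, 0.1, 2005))
  # rho is irrelevant when sigma = 0
  hp2 <- flat_hyperparams(cpr_asymptote = 0.6, cpr_rate = 0.1,
                          cpr_midpoint = 2005, rho = 0.95)
  tr2 <- simulate_true_trajectories(h, 1990:2030, hp2, seed = 9)
  expect_equal(tr2$cpr_total, tr$cpr_total)
})

test_that("rate zero gives flat trajectories", {
  tr <- simulate_true_trajectories(
    tiny_hierarchy(), 1995:2005,
    flat_hyperparams(cpr_rate = 1e-12), seed = 2)
  expect_true(all(abs(tr$cpr_total - tr$cpr_total[, 1]) < 1e-9))
})

test_that("generated proportions respect the accounting bounds", {
  h <- make_hierarchy(2, 3)
  for (seed in 1:5) {
    tr <- simulate_true_trajectories(h, 1990:2030, seed = seed)
    for (q in c("cpr_total", "r_modern", "mcpr", "traditional", "unmet_any")) {
      expect_true(all(tr[[q]] >= 0 & tr[[q]] <= 1))
    }
    expect_true(all(tr$cpr_total + tr$unmet_any <= 1))
    expect_equal(tr$mcpr + tr$traditional, tr$cpr_total)
  }
  # reproducibility
  t1 <- simulate_true_trajectories(h, 1990:2030, seed = 42)
  t2 <- simulate_true_trajectories(h, 1990:2030, seed = 42)
  expect_identical(t1$cpr_total, t2$cpr_total)
  expect_error(simulate_true_trajectories(h, 2030:1990), "non-decreasing")
})

test_that("surveys have one row per design row and honour zero noise", {
  h <- tiny_hierarchy()
  tr <- simulate_true_trajectories(h, 1990:2030, seed = 3)
  des <- fp_survey_design(h, years = c(1998, 2004, 2011))
  expect_equal(nrow(des), 12) # 4 areas x 3 survey years
  obs <- simulate_surveys(tr, des, seed = 4)
  expect_equal(nrow(obs), 12)

  des_inf <- des
  des_inf$n_eff <- Inf
  obs_inf <- simulate_surveys(tr, des_inf, seed = 5)
  ridx <- match(obs_inf$area_id, rownames(tr$cpr_total))
  yix <- match(obs_inf$year, tr$years)
  expect_equal(obs_inf$cpr_total,
               unname(tr$cpr_total[cbind(ridx, yix)]))

  bad <- des
  bad$area_id[1] <- "nope"
  expect_error(simulate_surveys(tr, bad, seed = 1), "unknown area")
})

test_that("survey sampling error matches the binomial formula", {
  # truth pinned at cpr_total = 0.3 via the midpoint identity
  h <- tiny_hierarchy()
  hp <- flat_hyperparams(cpr_asymptote = 0.6, cpr_rate = 0.1,
                         cpr_midpoint = 2005)
  tr <- simulate_true_trajectories(h, 2000:2010, hp, seed = 1)
  des <- data.frame(area_id = "C", year = 2005, source_type = "DHS",
                    n_eff = 100, components = "cpr_total")
  des <- des[rep(1, 1000), ]
  obs <- simulate_surveys(tr, des, seed = 6)
  target <- sqrt(0.3 * 0.7 / 100) # 0.0458
  mc_se <- target / sqrt(2 * (1000 - 1))
  expect_lt(abs(sd(obs$cpr_total) - target), 3 * mc_se + 1e-3)

  # MICS rows carry the SD inflation factor (default 1.5)
  des_m <- des
  des_m$source_type <- "MICS"
  obs_m <- simulate_surveys(tr, des_m, seed = 7)
  expect_gt(sd(obs_m$cpr_total) / sd(obs$cpr_total), 1.3)
  expect_lt(sd(obs_m$cpr_total) / sd(obs$cpr_total), 1.7)
})

test_that("population counts nest exactly and honour settings", {
  h <- make_hierarchy(2, c(3, 2))
  pops <- simulate_population(h, 2000:2005, seed = 8)
  for (yr in 2000:2005) {
    p <- pops[pops$year == yr, ]
    cnt <- function(a) p$mwra[p$area_id == a]
    for (r in c("R01", "R02")) {
      dv <- h$area_id[h$level == "division" & h$parent_id == r]
      expect_equal(sum(vapply(dv, cnt, numeric(1))), cnt(r))
    }
    expect_equal(cnt("R01") + cnt("R02"), cnt("C"))
  }
  expect_true(all(pops$mwra > 0))

  flat <- simulate_population(h, 2000:2005,
                              fp_population_settings(growth_rate = 0),
                              seed = 9)
  expect_equal(length(unique(flat$mwra[flat$area_id == "C"])), 1)
  expect_identical(simulate_population(h, 2000:2002, seed = 10),
                   simulate_population(h, 2000:2002, seed = 10))
})

test_that("services data stay positive with poverty in (0, 1)", {
  sv <- simulate_services(c("R01", "R02"), 2020:2030, seed = 11)
  expect_true(all(sv$hrh > 0 & sv$fh > 0 & sv$hb > 0))
  expect_true(all(sv$poverty_rate > 0 & sv$poverty_rate < 1))
  expect_identical(sv, simulate_services(c("R01", "R02"), 2020:2030,
                                         seed = 11))
  still <- fp_services_settings(trend = 0, sd_region = 0, sd_noise = 0,
                                poverty_sd = 0)
  sv0 <- simulate_services(c("R01", "R02"), 2020:2021, still, seed = 12)
  expect_equal(length(unique(sv0$hrh)), 1)
  expect_equal(length(unique(sv0$poverty_rate)), 1)
})
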