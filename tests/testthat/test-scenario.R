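# deterministic panel where ln(mcpr) = a + b ln(provision) + c ln(utilization)
make_link_panel <- function(a = -2, b = 0.5, cc = 0.3, regions = c("R01", "R02"),
                            years = 2020:2030, seed = 31) {
  set.seed(seed)
  rows <- list()
  for (r in regions) {
    prov <- exp(rnorm(length(years), 0, 0.3))
    util <- exp(rnorm(length(years), 0, 0.3))
    mcpr <- exp(a + b * log(prov) + cc * log(util))
    rows[[r]] <- data.frame(area_id = r, year = years, provision = prov,
                            utilization = util, mcpr = mcpr)
  }
  do.call(rbind, rows)
}

fit_link_from_panel <- function(panel, ...) {
  # noiseless panels trigger lm's perfect-fit warning; irrelevant here
  suppressWarnings(fit_link(panel[, c("area_id", "year", "mcpr")],
           data.frame(area_id = panel$area_id, year = panel$year,
                      provision = panel$provision),
           data.frame(area_id = panel$area_id, year = panel$year,
                      utilization = panel$utilization), ...))
}

test_that("provision index is the product of components", {
  sv <- data.frame(area_id = "R01", year = 2020:2022,
                   hrh = 1, fh = 1, hb = 1, poverty_rate = 0.3)
  expect_equal(provision_index(sv)$provision, rep(1, 3))
  sv2 <- sv; sv2$hb <- 2
  expect_equal(provision_index(sv2)$provision,
               2 * provision_index(sv)$provision)
  svn <- sv; svn$hrh <- c(2, 3, 4)
  norm <- provision_index(svn, normalize_base = 2020)
  expect_equal(norm$provision[norm$year == 2020], 1)
  svb <- sv; svb$fh <- -1
  expect_error(provision_index(svb), "positive")
})

test_that("utilization index couples demand and affordability", {
  d <- data.frame(area_id = "R01", year = 2020:2022,
                  demand = c(0.5, 0.4, 0.3))
  sv <- data.frame(area_id = "R01", year = 2020:2022,
                   poverty_rate = c(0.375, 1, 0))
  u <- utilization_index(d, sv)
  expect_equal(u$utilization, c(0.5 * 0.625, 0, 0.3))
})

test_that("reductions compound multiplicatively from the start year", {
  yrs <- 2020:2030
  v <- rep(10, 11)
  expect_equal(apply_reduction(v, yrs, 0, 2020), v)
  r25 <- apply_reduction(v, yrs, 0.25, 2020)
  expect_equal(r25[11] / v[11], 0.75^10)
  expect_equal(round(r25[11] / v[11], 6), 0.056314)
  r5 <- apply_reduction(v, yrs, 0.05, 2020)
  expect_equal(r5[2] / v[2], 0.95)
  # values before the start year are untouched
  pre <- apply_reduction(v, yrs, 0.25, 2025)
  expect_equal(pre[1:5], v[1:5])
  expect_error(apply_reduction(v, yrs, 1, 2020), "rate")
})

test_that("noiseless log-linear coefficients are recovered exactly", {
  panel <- make_link_panel(a = -2, b = 0.5, cc = 0.3)
  link <- fit_link_from_panel(panel)
  expect_lt(abs(link$b_provision - 0.5), 1e-8)
  expect_lt(abs(link$c_utilization - 0.3), 1e-8)
  expect_true(link$retained)

  # destroying the association by permutation rejects the screen
  set.seed(32)
  shuf <- panel
  shuf$mcpr <- exp(-2 + 0.3 * log(shuf$utilization)) *
    exp(rnorm(nrow(shuf), 0, 0.2))
  shuf$provision <- sample(shuf$provision)
  link2 <- fit_link_from_panel(shuf)
  expect_false(link2$retained)

  # constant predictor is a singular fit
  cst <- panel; cst$provision <- 1
  expect_error(fit_link_from_panel(cst), "singular")
})

test_that("null-association retention is near alpha squared", {
  set.seed(33)
  years <- 2020:2030
  retained <- logical(300)
  for (i in seq_along(retained)) {
    prov <- exp(rnorm(11, 0, 0.3))
    util <- exp(rnorm(11, 0, 0.3))
    mcpr <- exp(-2 + rnorm(11, 0, 0.3))
    panel <- data.frame(area_id = "R01", year = years, provision = prov,
                        utilization = util, mcpr = pmin(mcpr, 0.9))
    retained[i] <- fit_link_from_panel(panel)$retained
  }
  # alpha^2 = 0.0025 for independent predictors; allow Monte-Carlo slack
  expect_lt(mean(retained), 0.03)
})

test_that("scenario projection covers the grid with the right structure", {
  panel <- make_link_panel()
  link <- fit_link_from_panel(panel)
  res <- project_scenarios(link)
  # 16 scenarios per region, full year span
  for (r in unique(panel$area_id)) {
    sub <- res[res$area_id == r, ]
    expect_equal(nrow(unique(sub[, c("x", "y")])), 16)
    expect_equal(sort(unique(sub$year)), 2020:2030)
  }
  # x = y = 0 reproduces the baseline prediction to machine precision
  base <- attr(res, "baseline")
  zero <- res[res$x == 0 & res$y == 0 & res$area_id == "R01", ]
  expect_equal(zero$mcpr, base$mcpr[base$area_id == "R01"],
               tolerance = 1e-14)
  # pointwise non-increasing in x at fixed y (positive elasticity)
  for (yl in unique(res$y)) {
    m <- sapply(sort(unique(res$x)), function(xx)
      res$mcpr[res$area_id == "R01" & res$x == xx & res$y == yl &
                 res$year == 2030])
    expect_true(all(diff(m) <= 1e-12))
  }

  # a rejected link refuses to project
  set.seed(34)
  bad <- panel
  bad$mcpr <- exp(-2 + rnorm(nrow(bad), 0, 0.3))
  link_bad <- fit_link_from_panel(bad)
  expect_false(link_bad$retained)
  expect_error(project_scenarios(link_bad), "rejected")
})

test_that("equal elasticities make the multiplier symmetric in (x, y)", {
  panel <- make_link_panel(b = 0.4, cc = 0.4, seed = 35)
  link <- fit_link_from_panel(panel)
  res <- project_scenarios(link)
  a <- res[res$x == 0.05 & res$y == 0.10 & res$area_id == "R01", "mcpr"]
  b <- res[res$x == 0.10 & res$y == 0.05 & res$area_id == "R01", "mcpr"]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("cumulative deltas are zero at baseline and ordered in severity", {
  panel <- make_link_panel(seed = 36)
  link <- fit_link_from_panel(panel)
  res <- project_scenarios(link)
  deltas <- cumulative_change(res)
  z <- deltas[deltas$x == 0 & deltas$y == 0, ]
  expect_true(all(abs(z$delta_vs_baseline) < 1e-12))
  for (r in unique(deltas$area_id)) {
    for (yl in unique(deltas$y)) {
      d <- deltas[deltas$area_id == r & deltas$y == yl, ]
      d <- d[order(d$x), ]
      expect_true(all(diff(d$delta_vs_baseline) <= 1e-12))
    }
  }

  # under a large reduction the 2030 level falls below the 2020 level
  panel2 <- make_link_panel(a = log(0.2), b = 0.5, cc = 0.3, seed = 37)
  link2 <- fit_link_from_panel(panel2)
  res2 <- project_scenarios(link2)
  d2 <- cumulative_change(res2)
  lg <- d2[d2$x == 0.25 & d2$y == 0.25, ]
  expect_true(all(lg$delta_vs_start < 0))
  expect_true(all(lg$below_start))
})

test_that("scenario grid carries the canonical labels", {
  g <- scenario_grid()
  expect_equal(nrow(g), 16)
  expect_setequal(unique(g$x), c(0, 0.05, 0.10, 0.25))
  expect_equal(g$x_label[g$x == 0.25][1], "large")
  expect_equal(g$y_label[g$y == 0][1], "none")
})
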