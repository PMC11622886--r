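test_that("demand satisfied handles edge cases and is scale-free", {
  expect_equal(demand_satisfied(0, 0.3), 0)
  expect_equal(demand_satisfied(0, 0), 0)
  expect_equal(demand_satisfied(0.2, 0.2), 0.5)
  expect_error(demand_satisfied(-0.1, 0.2), "non-negative")
  set.seed(21)
  m <- runif(50); u <- runif(50); k <- runif(50, 0.1, 10)
  expect_equal(demand_satisfied(k * m, k * u), demand_satisfied(m, u))
})

test_that("unmet need for modern methods adds traditional users", {
  expect_equal(unmet_modern(0.10, 0.05), 0.15)
  expect_equal(unmet_modern(0.2, 0), 0.2)
  expect_error(unmet_modern(0.5, 0.4, mcpr = 0.3), "exceeds 1")
})

test_that("counts scale rates by the base population", {
  expect_equal(fp_counts(0.2, 1000), 200)
  expect_equal(fp_counts(0, 5e6), 0)
  expect_equal(fp_counts(1, 58000), 58000)
  expect_error(fp_counts(1.2, 10), "rate")
})

test_that("annual change matches hand arithmetic and flags the benchmark", {
  years <- 2014:2021
  S <- 100
  flat <- matrix(0.25, S, length(years))
  post <- build_posterior(flat, flat * 0.2, flat * 0.5, years)
  ac <- annual_change(post, "A", c(2015, 2020))
  expect_equal(ac$median, 0)
  expect_equal(ac$lower95, 0)
  expect_false(ac$attained_cri)

  rising <- matrix(rep(0.10 + 0.01 * (years - 2014), each = S),
                   S, length(years))
  post2 <- build_posterior(rising, rising * 0, rising * 0.5, years)
  ac2 <- annual_change(post2, "A", c(2015, 2020))
  expect_equal(ac2$median, 1.0)
  expect_equal(ac2$upper95, 1.0)

  # draws engineered so the 2.5th percentile of the change is above 1.4
  set.seed(22)
  slopes <- qunif(seq(0.001, 0.999, length.out = S), 0.045, 0.093)
  eng <- outer(slopes, years - 2015) * (years[1] <= 2015) + 0.05
  eng <- pmax(pmin(eng, 0.95), 0)
  post3 <- build_posterior(eng, eng * 0, eng * 0, years)
  ac3 <- annual_change(post3, "A", c(2015, 2020))
  expect_gte(ac3$lower95, 4.5 - 0.2)
  expect_true(ac3$attained_cri)

  expect_error(annual_change(post, "A", c(2020, 2015)), "year1 > year0")
})

test_that("attainment probability is the exact draw fraction", {
  years <- 2029:2030
  S <- 200
  ds_target <- c(rep(0.80, 100), rep(0.70, 100))
  mcpr <- matrix(0.3, S, 2)
  unmet <- 0.3 / ds_target - 0.3 # gives ds exactly 0.80 / 0.70 in 2030
  tra <- matrix(0, S, 2)
  um <- cbind(rep(0.2, S), unmet)
  post <- build_posterior(mcpr, tra, um, years)
  expect_equal(attainment_probability(post, "A"), 50.0)
  expect_equal(attainment_probability(post, "A",
                                      target_spec(ds_threshold = 0.69)),
               100.0)
  p0 <- attainment_probability(post, "A", target_spec(ds_threshold = 0.81))
  expect_equal(p0, 0)
  expect_equal(format_attainment(p0), "..")

  # monotone non-increasing in the threshold
  th <- seq(0.5, 0.95, by = 0.05)
  probs <- vapply(th, function(t)
    attainment_probability(post, "A", target_spec(ds_threshold = t)),
    numeric(1))
  expect_true(all(diff(probs) <= 0))
})

test_that("required increase reproduces the worked arithmetic", {
  years <- c(2022, 2030)
  S <- 50
  # demand 2030 = 50% in every draw, mcpr 2022 = 20%
  mcpr <- cbind(rep(0.20, S), rep(0.25, S))
  tra <- matrix(0, S, 2)
  um <- cbind(rep(0.10, S), rep(0.25, S)) # demand 2030 = 0.25 + 0.25 = 0.5
  post <- build_posterior(mcpr, tra, um, years)
  pops <- const_pop("A", years, mwra = 8e6)
  ri <- required_increase(post, pops, "A")
  expect_equal(ri$pct$median, 100 * (0.75 * 0.5 - 0.20)) # 17.5 %p
  # users: 0.75 * (0.5 * 8e6) - 0.20 * 8e6 = 3e6 - 1.6e6
  expect_equal(ri$users$median, 0.75 * 4e6 - 1.6e6)

  # percentage requirement is invariant to population size; users scale
  pops10 <- const_pop("A", years, mwra = 8e7)
  ri10 <- required_increase(post, pops10, "A")
  expect_equal(ri10$pct$median, ri$pct$median)
  expect_equal(ri10$users$median, 10 * ri$users$median)

  expect_error(required_increase(post, const_pop("A", 2030, 1e6), "A"),
               "missing for area A, year 2022")

  # 0.75 * 4M demand count minus 1M users = 2M additional users
  mcpr2 <- cbind(rep(0.25, S), rep(0.25, S))
  um2 <- cbind(rep(0.10, S), rep(0.75, S)) # demand 2030 = 1.0
  post2 <- build_posterior(mcpr2, tra, um2, years)
  pops2 <- const_pop("A", years, mwra = 4e6)
  ri2 <- required_increase(post2, pops2, "A")
  expect_equal(ri2$users$median, 0.75 * 4e6 - 1e6) # 2M
})

test_that("aggregation consistency reports no gap for identical series", {
  years <- 2015:2020
  S <- 80
  m <- matrix(0.3, S, length(years))
  sub <- array(NA_real_, c(S, 2, length(years), 1),
               dimnames = list(NULL, c("D1", "D2"), years, "mcpr"))
  sub[, 1, , 1] <- m; sub[, 2, , 1] <- m
  nat <- array(m, c(S, 1, length(years), 1),
               dimnames = list(NULL, "C", years, "mcpr"))
  pops <- const_pop(c("D1", "D2", "C"), years, mwra = 1e5)
  res <- aggregate_consistency(fp_posterior(sub), fp_posterior(nat), pops)
  expect_equal(res$mean_gap, 0)
  expect_equal(res$p_value, 1)
  expect_false(any(res$per_year$flagged))

  nat_short <- nat[, , 1:3, , drop = FALSE]
  dimnames(nat_short) <- list(NULL, "C", years[1:3], "mcpr")
  expect_error(aggregate_consistency(sub, nat_short, pops), "grids differ")
})

test_that("posterior constructor enforces the identity set", {
  years <- 2020:2021
  S <- 10
  post <- build_posterior(matrix(0.2, S, 2), matrix(0.1, S, 2),
                          matrix(0.15, S, 2), years)
  expect_s3_class(post, "fp_posterior")
  broken <- unclass(post)
  broken[, 1, 1, "traditional"] <- 0.5
  expect_error(fp_posterior(broken), "identity violated")
  expect_error(summarize_posterior(post, quantities = "nope"),
               "unknown quantity")
})
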