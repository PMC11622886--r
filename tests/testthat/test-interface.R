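test_that("survey tables round-trip through CSV", {
  h <- tiny_hierarchy()
  tr <- simulate_true_trajectories(h, 1990:2030, seed = 51)
  obs <- simulate_surveys(tr, fp_survey_design(h), seed = 52)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surveys(obs, path)
  back <- read_surveys(path)
  expect_equal(back, obs, tolerance = 1e-12)
})

test_that("survey reader rejects out-of-schema input with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(area_id = "C", year = 2010, source_type = "DHS",
                  n_eff = 100, cpr_total = 1.2, mcpr = NA, traditional = NA,
                  unmet_any = NA)
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_surveys(path), "row 1, column cpr_total")

  d$cpr_total <- 0.5; d$source_type <- "CENSUS"
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_surveys(path), "unknown source_type")

  d$source_type <- "DHS"; d$bogus <- 1
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_surveys(path), "unknown column")

  utils::write.csv(d[0, names(d) != "bogus"], path, row.names = FALSE)
  expect_warning(empty <- read_surveys(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("estimates are formatted the way the reports print them", {
  expect_equal(format_estimate(16.4, 13.1, 20.2), "16.4 (13.1–20.2)")
  expect_equal(format_estimate(0.5, 0.5, 0.5), "0.5 (0.5–0.5)")
  expect_equal(format_attainment(0), "..")
  expect_equal(format_attainment(90), "90.0")
  expect_equal(percent1(0.37584), 37.6)
  # half-even rounding at the boundary
  expect_equal(percent1(0.12345), 12.3)
  expect_equal(percent1(0.12355), 12.4)
})

test_that("cli returns usage exit codes without touching the filesystem", {
  expect_equal(suppressMessages(fpemsub_cli(character(0))), 2L)
  expect_equal(suppressMessages(fpemsub_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(fpemsub_cli("fit")), 2L)
  expect_equal(suppressMessages(fpemsub_cli(c("fit", "--seed", "3"))), 2L)
  expect_equal(suppressMessages(
    fpemsub_cli(c("all", "--config", "no-such-file.yaml"))), 1L)
})

test_that("the pipeline runs end to end, deterministically per seed", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(seed = 5, out_dir = out1,
              years = list(start = 2005, end = 2030),
              hierarchy = list(n_regions = 2, divisions_per_region = 2),
              simulate = TRUE,
              model = list(chains = 2, warmup = 150, draws = 150),
              scenario = list(start_year = 2020, end_year = 2030))
  m1 <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  expect_true(file.exists(file.path(out1, "summaries.csv")))
  expect_true(file.exists(file.path(out1, "attainment.csv")))
  expect_true(file.exists(file.path(out1, "table1.csv")))
  expect_true(file.exists(file.path(out1, "link_screen.csv")))
  expect_true(file.exists(file.path(out1, "manifest.csv")))
  # the fitted summaries are re-readable and well-formed
  s <- utils::read.csv(file.path(out1, "summaries.csv"))
  expect_true(all(s$lower95 <= s$median & s$median <= s$upper95))

  cfg$out_dir <- out2
  m2 <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  shared <- intersect(m1$file, m2$file)
  # config.yaml embeds out_dir and run_metadata.txt hashes it
  shared <- setdiff(shared, c("config.yaml", "run_metadata.txt"))
  expect_equal(m1$md5[match(shared, m1$file)],
               m2$md5[match(shared, m2$file)])

  # configuration errors surface before any fitting
  bad <- cfg
  bad$simulate <- FALSE
  bad$inputs <- list(surveys = "missing.csv", populations = "missing.csv",
                     services = "missing.csv")
  expect_error(suppressMessages(run_pipeline(bad)), "missing or not found")
})
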