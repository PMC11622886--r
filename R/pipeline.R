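# End-to-end orchestration: YAML run configuration, staged pipeline with a
# checksummed artefact manifest, and a small command-line front end.

#' Load and validate a run configuration
#'
#' The YAML layout (all blocks optional unless a stage needs them):
#' ```yaml
#' seed: 1
#' out_dir: runs/demo
#' years: {start: 1990, end: 2030}
#' hierarchy: {n_regions: 2, divisions_per_region: 3}
#' simulate: true            # generate inputs; otherwise give paths below
#' inputs: {surveys: s.csv, populations: p.csv, services: v.csv}
#' model: {chains: 2, warmup: 300, draws: 300}
#' targets: {ds_threshold: 0.75, ds_target_year: 2030}
#' scenario: {start_year: 2020, end_year: 2030}
#' ```
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated list of class `fp_run_config`.
#' @export
fp_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    assert_that(file.exists(path), "config file not found: %s", path)
    yaml::read_yaml(path)
  } else path
  assert_that(!is.null(cfg$seed), "config must set a seed")
  assert_that(!is.null(cfg$out_dir), "config must set out_dir")
  cfg$years <- cfg$years %||% list(start = 1990, end = 2030)
  cfg$simulate <- isTRUE(cfg$simulate)
  if (!cfg$simulate) {
    for (f in c("surveys", "populations", "services")) {
      p <- cfg$inputs[[f]]
      assert_that(!is.null(p) && file.exists(p),
                  "input file for '%s' missing or not found", f)
    }
  } else {
    assert_that(!is.null(cfg$hierarchy$n_regions),
                "simulate: true requires a hierarchy block")
  }
  cfg$model <- cfg$model %||% list()
  structure(cfg, class = "fp_run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: `simulate` (optional input generation), `fit`, `indicators`,
#' `scenarios`, `report`. Every output file is listed in `manifest.txt`
#' with its MD5 checksum; the resolved seed and a hash of the configuration
#' are logged to `run_metadata.txt`. Deterministic for a fixed seed.
#'
#' @param config an [fp_run_config()] (or path to one).
#' @param stages subset of stages to run (dependencies are not re-run; a
#'   `fit` stage requires inputs present in `out_dir` or via config).
#' @param seed optional override of the config seed.
#' @return invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "indicators",
                                    "scenarios", "report"),
                         seed = NULL) {
  if (!inherits(config, "fp_run_config")) config <- fp_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed %||% config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  years <- config$years$start:config$years$end
  artefacts <- character(0)
  t_all <- proc.time()[3]
  stage_msg <- function(s, t0) {
    message(sprintf("[fpemsub] stage %-10s %6.1fs", s, proc.time()[3] - t0))
  }

  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  meta <- c(sprintf("seed: %d", seed),
            sprintf("config_md5: %s", unname(tools::md5sum(cfg_file))),
            sprintf("package_version: %s",
                    as.character(utils::packageVersion("fpemsub"))))
  writeLines(meta, file.path(out, "run_metadata.txt"))
  artefacts <- c(artefacts, cfg_file, file.path(out, "run_metadata.txt"))

  hier <- if (!is.null(config$hierarchy$n_regions)) {
    make_hierarchy(config$hierarchy$n_regions,
                   unlist(config$hierarchy$divisions_per_region))
  } else NULL

  paths <- list(surveys = file.path(out, "surveys.csv"),
                populations = file.path(out, "populations.csv"),
                services = file.path(out, "services.csv"))

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    truth <- simulate_true_trajectories(hier, years, seed = seed)
    svy_years <- intersect(c(1991, 1998, 2000, 2004, 2006, 2011, 2014, 2018),
                           years)
    assert_that(length(svy_years) >= 2,
                "the year grid covers fewer than two default survey years")
    design <- fp_survey_design(hier, years = svy_years)
    surveys <- simulate_surveys(truth, design, seed = seed + 1L)
    pops <- simulate_population(hier, years, seed = seed + 2L)
    svc <- simulate_services(area_ids(hier, "region"), years,
                             seed = seed + 3L)
    write_surveys(surveys, paths$surveys)
    write_populations(pops, paths$populations)
    write_services(svc, paths$services)
    artefacts <- c(artefacts, unlist(paths))
    stage_msg("simulate", t0)
  } else if (!config$simulate) {
    paths <- config$inputs
  }

  fit <- NULL
  if (any(c("fit", "indicators", "scenarios", "report") %in% stages)) {
    t0 <- proc.time()[3]
    if (any(!file.exists(unlist(paths[c("surveys", "populations")])))) {
      fp_stop("fit stage: input tables not found (run the simulate stage or point config$inputs at existing files)")
    }
    if ("scenarios" %in% stages && !file.exists(paths$services)) {
      fp_stop("scenarios stage requires a services table; none configured")
    }
    surveys <- read_surveys(paths$surveys)
    pops <- read_populations(paths$populations)
    if (is.null(hier)) {
      fp_stop("a hierarchy block is required to fit")
    }
    mc <- config$model
    fcfg <- fpem_config(years = years, chains = mc$chains %||% 2,
                        warmup = mc$warmup %||% 300,
                        draws = mc$draws %||% 300, seed = seed)
    fit <- fpem_fit(surveys, hier, pops, fcfg)
    summ <- summary(fit)
    utils::write.csv(summ, file.path(out, "summaries.csv"),
                     row.names = FALSE)
    artefacts <- c(artefacts, file.path(out, "summaries.csv"))
    stage_msg("fit", t0)
  }

  spec <- do.call(target_spec, config$targets %||% list())
  if ("indicators" %in% stages && !is.null(fit)) {
    t0 <- proc.time()[3]
    rep1 <- attainment_report(fit, spec = spec)
    utils::write.csv(rep1, file.path(out, "attainment.csv"),
                     row.names = FALSE)
    artefacts <- c(artefacts, file.path(out, "attainment.csv"))
    stage_msg("indicators", t0)
  }

  if ("scenarios" %in% stages && !is.null(fit)) {
    t0 <- proc.time()[3]
    svc <- read_services(paths$services)
    sc <- config$scenario %||% list()
    sy <- sc$start_year %||% 2020
    ey <- sc$end_year %||% 2030
    regions <- area_ids(fit$hierarchy, "region")
    base <- summarize_posterior(fit, "mcpr", areas = regions,
                                years = sy:ey)
    ind <- data.frame(area_id = base$area_id, year = base$year,
                      mcpr = base$median)
    dem <- summarize_posterior(fit, "demand_modern", areas = regions,
                               years = sy:ey)
    demand <- data.frame(area_id = dem$area_id, year = dem$year,
                         demand = dem$median)
    svc_sub <- svc[svc$year %in% sy:ey, ]
    prov <- provision_index(svc_sub, normalize_base = sy)
    util <- utilization_index(demand, svc_sub)
    link <- fit_link(ind, prov, util)
    if (link$retained) {
      res <- project_scenarios(link, start_year = sy)
      utils::write.csv(as.data.frame(res), file.path(out, "scenarios.csv"),
                       row.names = FALSE)
      deltas <- cumulative_change(res)
      utils::write.csv(deltas, file.path(out, "scenario_deltas.csv"),
                       row.names = FALSE)
      artefacts <- c(artefacts, file.path(out, "scenarios.csv"),
                     file.path(out, "scenario_deltas.csv"))
    } else {
      warning("link model rejected by the significance screen; scenario projections skipped",
              call. = FALSE)
    }
    screen <- data.frame(indicator = link$label,
                         b_provision = link$b_provision,
                         p_provision = link$p_provision,
                         c_utilization = link$c_utilization,
                         p_utilization = link$p_utilization,
                         retained = link$retained)
    utils::write.csv(screen, file.path(out, "link_screen.csv"),
                     row.names = FALSE)
    artefacts <- c(artefacts, file.path(out, "link_screen.csv"))
    stage_msg("scenarios", t0)
  }

  if ("report" %in% stages && !is.null(fit)) {
    t0 <- proc.time()[3]
    tab1 <- format_table1(fit, spec = spec)
    utils::write.csv(tab1, file.path(out, "table1.csv"), row.names = FALSE)
    cnts <- format_counts_table(fit, year = spec$reference_year_for_users)
    utils::write.csv(cnts, file.path(out, "counts.csv"), row.names = FALSE)
    artefacts <- c(artefacts, file.path(out, "table1.csv"),
                   file.path(out, "counts.csv"))
    stage_msg("report", t0)
  }

  manifest <- data.frame(file = basename(artefacts),
                         md5 = unname(tools::md5sum(artefacts)))
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  message(sprintf("[fpemsub] pipeline done in %.1fs; %d artefacts in %s",
                  proc.time()[3] - t_all, nrow(manifest), out))
  invisible(manifest)
}

cli_usage <- function() {
  paste(
    "usage: fpemsub <subcommand> --config <file.yaml> [--seed <int>] [--out <dir>]",
    "subcommands: simulate | fit | indicators | scenarios | report | all",
    sep = "\n")
}

#' Command-line entry point
#'
#' Thin wrapper over [run_pipeline()]. Returns 0 on success, 2 on usage
#' errors (unknown subcommand, missing `--config`), 1 on runtime failure.
#' Progress is logged to stderr.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return integer exit status, invisibly.
#' @export
fpemsub_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "fit", "indicators", "scenarios", "report",
                   "all")
  if (length(args) == 0 || !args[1] %in% subcommands) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--config", "--seed", "--out") || i == length(args)) {
      message("unrecognised or valueless flag: ", key, "\n", cli_usage())
      return(invisible(2L))
    }
    opt[[sub("^--", "", key)]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) {
    message("missing required flag: --config\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- fp_run_config(opt$config)
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    stages <- if (sub == "all") {
      c("simulate", "fit", "indicators", "scenarios", "report")
    } else sub
    if (!cfg$simulate) stages <- setdiff(stages, "simulate")
    run_pipeline(cfg, stages = stages,
                 seed = if (!is.null(opt$seed)) as.integer(opt$seed))
    0L
  }, error = function(e) {
    message("[fpemsub] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
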