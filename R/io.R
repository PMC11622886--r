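# CSV schemas and formatted report output. All files are UTF-8 CSV with a
# period decimal separator; proportions are stored as fractions in files
# and become percentages only in formatted reports.

survey_columns <- c("area_id", "year", "source_type", "n_eff",
                    "cpr_total", "mcpr", "traditional", "unmet_any")

#' Read a survey observation table
#'
#' Validates the documented schema: `area_id`, `year`, `source_type`
#' (DHS/MICS), `n_eff`, and the component columns `cpr_total`, `mcpr`,
#' `traditional`, `unmet_any` (missing values allowed and preserved).
#' Optional `*_se` columns carry pre-computed sampling errors.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_surveys <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(d), c(survey_columns,
                                 paste0(survey_columns[5:8], "_se")))
  assert_that(length(unknown) == 0,
              "unknown column(s) in %s: %s", path,
              paste(unknown, collapse = ", "))
  missing <- setdiff(c("area_id", "year", "source_type"), names(d))
  assert_that(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  if (nrow(d) == 0) {
    warning("empty survey table: ", path, call. = FALSE)
    return(d)
  }
  bad_src <- !d$source_type %in% c("DHS", "MICS")
  if (any(bad_src)) {
    fp_stop("row %d: unknown source_type '%s'", which(bad_src)[1],
            d$source_type[which(bad_src)[1]])
  }
  for (q in intersect(c("cpr_total", "mcpr", "traditional", "unmet_any"),
                      names(d))) {
    bad <- !is.na(d[[q]]) & (d[[q]] < 0 | d[[q]] > 1)
    if (any(bad)) {
      fp_stop("row %d, column %s: proportion %g outside [0, 1]",
              which(bad)[1], q, d[[q]][which(bad)[1]])
    }
  }
  d
}

#' Write a survey observation table
#'
#' @param surveys data frame in the [read_surveys()] schema.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write MWRA population counts (`area_id`, `year`, `mwra`)
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_populations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("area_id", "year", "mwra") %in% names(d)),
              "populations need columns area_id, year, mwra")
  assert_that(all(d$mwra >= 0), "population counts must be non-negative")
  d
}

#' @rdname read_populations
#' @param populations data frame to write.
#' @export
write_populations <- function(populations, path) {
  utils::write.csv(populations, path, row.names = FALSE)
  invisible(path)
}

#' Read/write regional services data
#' (`area_id`, `year`, `hrh`, `fh`, `hb`, `poverty_rate`)
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_services <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "year", "hrh", "fh", "hb", "poverty_rate")
  assert_that(all(need %in% names(d)),
              "services need columns %s", paste(need, collapse = ", "))
  assert_that(all(d$hrh > 0 & d$fh > 0 & d$hb > 0),
              "provision components must be positive")
  assert_that(all(d$poverty_rate >= 0 & d$poverty_rate <= 1),
              "poverty_rate must lie in [0, 1]")
  d
}

#' @rdname read_services
#' @param services data frame to write.
#' @export
write_services <- function(services, path) {
  utils::write.csv(services, path, row.names = FALSE)
  invisible(path)
}

#' Format a median and credible interval the way the tables print it
#'
#' @param median,lower,upper values already on the reporting scale.
#' @param digits decimals (default 1).
#' @return string `"median (lower-upper)"` with an en dash.
#' @export
#' @examples
#' format_estimate(16.4, 13.1, 20.2) # "16.4 (13.1–20.2)"
format_estimate <- function(median, lower, upper, digits = 1) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "–", fmt, ")"), median, lower, upper)
}

#' Format attainment probability with the zero sentinel
#'
#' @param p probability in percent.
#' @return `".."` for exactly zero, otherwise the value at 1 decimal.
#' @export
format_attainment <- function(p) {
  ifelse(p == 0, "..", sprintf("%.1f", p))
}

#' Assemble a formatted indicator table per area
#'
#' One row per area with "median (lower-upper)" strings (percent, 1
#' decimal) for use, unmet need and demand satisfied in the chosen years,
#' plus attainment probability (".." when zero) and required increases.
#'
#' @param fit an [fpem_fit()] object.
#' @param years two report years, estimation and projection.
#' @param spec a [target_spec()].
#' @param areas area ids (default all).
#' @return data frame of formatted strings.
#' @export
format_table1 <- function(fit, years = c(2015, 2030), spec = target_spec(),
                          areas = NULL) {
  areas <- areas %||% dimnames(fit$posterior)[[2]]
  cell <- function(a, q, yr) {
    s <- summarize_posterior(fit, quantities = q, areas = a, years = yr)
    format_estimate(100 * s$median, 100 * s$lower95, 100 * s$upper95)
  }
  rows <- lapply(areas, function(a) {
    ri <- if (!is.null(fit$populations)) {
      required_increase(fit, fit$populations, a, spec)
    } else NULL
    data.frame(
      area_id = a,
      use_y1 = cell(a, "mcpr", years[1]),
      use_y2 = cell(a, "mcpr", years[2]),
      unmet_y1 = cell(a, "unmet_modern", years[1]),
      unmet_y2 = cell(a, "unmet_modern", years[2]),
      ds_y1 = cell(a, "ds_modern", years[1]),
      ds_y2 = cell(a, "ds_modern", years[2]),
      attainment = format_attainment(attainment_probability(fit, a, spec)),
      required_pct = if (is.null(ri)) NA_character_ else
        format_estimate(ri$pct$median, ri$pct$lower95, ri$pct$upper95),
      required_users_thousands = if (is.null(ri)) NA_character_ else
        format_estimate(ri$users$median / 1e3, ri$users$lower95 / 1e3,
                        ri$users$upper95 / 1e3))
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("y1", years[1], names(out))
  names(out) <- sub("y2", years[2], names(out))
  out
}

#' Counts table (users, unmet need, demand satisfied, in thousands)
#'
#' Sample-wise counts of women using modern methods, with unmet need for
#' modern methods, and with satisfied demand, summarised per area for a
#' reference year.
#'
#' @param fit an [fpem_fit()] object with populations.
#' @param year reference year.
#' @param areas area ids (default all).
#' @return data frame with formatted "median (lower-upper)" count strings
#'   in thousands, 1 decimal.
#' @export
format_counts_table <- function(fit, year = 2022, areas = NULL) {
  assert_that(!is.null(fit$populations), "fit has no population counts")
  areas <- areas %||% dimnames(fit$posterior)[[2]]
  yr <- as.character(year)
  rows <- lapply(areas, function(a) {
    m <- fit$populations$mwra[fit$populations$area_id == a &
                                fit$populations$year == year]
    assert_that(length(m) == 1, "population missing for %s in %d", a, year)
    cellq <- function(q) {
      draws <- fp_counts(fit$posterior[, a, yr, q], m) / 1e3
      qq <- ci_quantiles(draws)
      format_estimate(qq["median"], qq["lower95"], qq["upper95"])
    }
    # demand satisfied counts: users among those with demand
    ds_draws <- fp_counts(fit$posterior[, a, yr, "mcpr"], m) / 1e3
    data.frame(area_id = a, year = year,
               users_thousands = cellq("mcpr"),
               unmet_thousands = cellq("unmet_modern"),
               demand_thousands = cellq("demand_modern"))
  })
  do.call(rbind, rows)
}
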