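#' Build a country-region-division area hierarchy
#'
#' Constructs the administrative tree that drives hierarchical pooling in
#' [fpem_fit()] and aggregation of counts. The tree always has a single
#' country root; every region is a child of the country and every division
#' a child of exactly one region (third-level units are not modelled).
#'
#' @param n_regions number of first-level units (regions), at least 1.
#' @param divisions_per_region either a single count applied to every
#'   region or an integer vector of length `n_regions`; every entry must be
#'   at least 1.
#' @param region_names optional character vector of region names.
#' @param country_name name of the root node.
#' @param seed unused placeholder kept for interface symmetry with the
#'   stochastic generators; the structure is fully deterministic.
#' @return An object of class `fp_hierarchy`: a data frame with columns
#'   `area_id`, `level` (country/region/division), `parent_id`, `name`.
#' @export
#' @examples
#' h <- make_hierarchy(2, 3)
#' table(h$level)
#' # Cameroon's layout: 10 regions, 58 divisions
#' hc <- make_hierarchy(10, cameroon_layout())
make_hierarchy <- function(n_regions, divisions_per_region,
                           region_names = NULL,
                           country_name = "National", seed = NULL) {
  assert_that(is_count(n_regions), "n_regions must be a positive integer")
  if (length(divisions_per_region) == 1L) {
    divisions_per_region <- rep(divisions_per_region, n_regions)
  }
  assert_that(length(divisions_per_region) == n_regions,
              "divisions_per_region must have length 1 or n_regions")
  assert_that(all(vapply(divisions_per_region, is_count, logical(1))),
              "every division count must be a positive integer")
  if (is.null(region_names)) {
    region_names <- names(divisions_per_region) %||%
      paste0("Region ", seq_len(n_regions))
  }
  assert_that(length(region_names) == n_regions,
              "region_names must have length n_regions")

  region_ids <- sprintf("R%02d", seq_len(n_regions))
  nodes <- data.frame(
    area_id = c("C", region_ids),
    level = c("country", rep("region", n_regions)),
    parent_id = c(NA_character_, rep("C", n_regions)),
    name = c(country_name, region_names),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(n_regions)) {
    k <- divisions_per_region[r]
    div <- data.frame(
      area_id = sprintf("%s.D%02d", region_ids[r], seq_len(k)),
      level = "division",
      parent_id = region_ids[r],
      name = sprintf("%s division %d", region_names[r], seq_len(k)),
      stringsAsFactors = FALSE
    )
    nodes <- rbind(nodes, div)
  }
  structure(nodes, class = c("fp_hierarchy", "data.frame"))
}

#' Cameroon's administrative layout
#'
#' Divisions per region for Cameroon's 10 regions and 58 divisions,
#' useful as the `divisions_per_region` argument of [make_hierarchy()].
#'
#' @return named integer vector of length 10 summing to 58.
#' @export
cameroon_layout <- function() {
  c(Adamawa = 5L, Centre = 10L, East = 4L, `Far North` = 6L,
    Littoral = 4L, North = 4L, Northwest = 7L, West = 8L,
    South = 4L, Southwest = 6L)
}

#' Validate an area hierarchy
#'
#' Checks the `fp_hierarchy` invariants: unique ids, exactly one parentless
#' country, regions parented by the country, divisions parented by regions,
#' and connectedness.
#'
#' @param hierarchy object to validate.
#' @return the hierarchy, invisibly, if valid; otherwise an error.
#' @export
validate_hierarchy <- function(hierarchy) {
  h <- as.data.frame(hierarchy)
  need <- c("area_id", "level", "parent_id", "name")
  assert_that(all(need %in% names(h)),
              "hierarchy must have columns %s", paste(need, collapse = ", "))
  assert_that(!anyDuplicated(h$area_id), "area_ids must be unique")
  cn <- h[h$level == "country", ]
  assert_that(nrow(cn) == 1L && is.na(cn$parent_id),
              "exactly one parentless country node is required")
  rg <- h[h$level == "region", ]
  assert_that(all(rg$parent_id == cn$area_id),
              "every region's parent must be the country")
  dv <- h[h$level == "division", ]
  assert_that(all(dv$parent_id %in% rg$area_id),
              "every division's parent must be a region")
  assert_that(all(h$level %in% c("country", "region", "division")),
              "unknown level in hierarchy")
  invisible(hierarchy)
}

area_ids <- function(hierarchy, level = NULL) {
  h <- as.data.frame(hierarchy)
  if (!is.null(level)) h <- h[h$level %in% level, ]
  h$area_id
}

parent_of <- function(hierarchy, area_id) {
  h <- as.data.frame(hierarchy)
  h$parent_id[match(area_id, h$area_id)]
}

children_of <- function(hierarchy, area_id) {
  h <- as.data.frame(hierarchy)
  h$area_id[!is.na(h$parent_id) & h$parent_id == area_id]
}

#' @export
print.fp_hierarchy <- function(x, ...) {
  tab <- table(factor(x$level, c("country", "region", "division")))
  cat("Area hierarchy:", tab["country"], "country,", tab["region"],
      "regions,", tab["division"], "divisions\n")
  invisible(x)
}
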