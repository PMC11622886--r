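# Shared fixtures: small hierarchies, quick fit configurations, and a
# constructor for posterior arrays with all accounting identities enforced.

quiet_fit <- function(...) suppressWarnings(fpem_fit(...))

tiny_hierarchy <- function() make_hierarchy(1, 2)

# deterministic hyperparameters: no AR(1) noise, no parent-child scatter
flat_hyperparams <- function(...) {
  fp_hyperparams(sigma_cpr = 0, sigma_mod = 0, sigma_unmet = 0,
                 sd_region = rep(0, 7), sd_division = rep(0, 7), ...)
}

quick_config <- function(years = 2000:2030, seed = 1, ...) {
  fpem_config(years = years, chains = 2, warmup = 200, draws = 200,
              seed = seed, ...)
}

# survey table with every component reported exactly at given values
exact_surveys <- function(area_id, years, cpr_total, mcpr, unmet_any,
                          n_eff = 1e5, source = "DHS") {
  data.frame(area_id = area_id, year = years, source_type = source,
             n_eff = n_eff, cpr_total = cpr_total, mcpr = mcpr,
             traditional = cpr_total - mcpr, unmet_any = unmet_any)
}

# posterior array for one area built from mcpr/traditional/unmet_any draws
# (matrices sample x year), with derived quantities computed sample-wise
build_posterior <- function(mcpr, traditional, unmet_any, years,
                            area = "A") {
  S <- nrow(mcpr)
  ny <- length(years)
  post <- array(NA_real_, c(S, 1, ny, 7),
                dimnames = list(NULL, area, years,
                                c("cpr_total", "mcpr", "traditional",
                                  "unmet_any", "unmet_modern",
                                  "demand_modern", "ds_modern")))
  post[, 1, , "mcpr"] <- mcpr
  post[, 1, , "traditional"] <- traditional
  post[, 1, , "cpr_total"] <- mcpr + traditional
  post[, 1, , "unmet_any"] <- unmet_any
  um <- unmet_any + traditional
  dm <- mcpr + um
  post[, 1, , "unmet_modern"] <- um
  post[, 1, , "demand_modern"] <- dm
  post[, 1, , "ds_modern"] <- ifelse(dm > 0, mcpr / dm, 0)
  fp_posterior(post)
}

const_pop <- function(areas, years, mwra) {
  expand.grid(area_id = areas, year = years, stringsAsFactors = FALSE) |>
    transform(mwra = mwra)
}
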