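# Subnational family-planning estimation model.
#
# Total prevalence and the modern share each follow a logistic growth trend
# with a stationary AR(1) distortion on the logit scale; unmet need follows
# a logit-linear relation to the total-prevalence trend with its own AR(1)
# distortion on the unmet/non-use ratio. Country-level parameters are fixed
# constants (point estimates from a previous country-level run, or the
# generator truth); region parameters are normal deviations around them and
# division parameters around their region (exchangeable pooling).
#
# Survey rows are transformed to logit-scale observations of total
# prevalence, the modern/total ratio, and the unmet/non-use ratio. Given
# the trend parameters the model is linear-Gaussian in the AR(1) states, so
# the states are marginalised analytically and the sampler only explores
# ~7 parameters per area plus 5 global parameters (rho, three innovation
# SDs, and the non-DHS variance inflation). Posterior trajectories are then
# reconstructed by conditional simulation of the AR(1) states.

fp_quantities <- c("cpr_total", "mcpr", "traditional", "unmet_any",
                   "unmet_modern", "demand_modern", "ds_modern")

#' Configuration for the subnational estimation model
#'
#' @param years annual estimation/projection grid.
#' @param chains number of MCMC chains (>= 2).
#' @param warmup,draws adaptation and retained iterations per chain.
#' @param thin keep every `thin`-th post-warmup iteration (`draws` are kept
#'   in total, so the chain runs `warmup + draws * thin` iterations).
#' @param seed integer seed; mandatory for the determinism contract.
#' @param country_params named list of fixed country-level parameters:
#'   `cpr_asymptote`, `cpr_rate`, `cpr_midpoint`, `mod_asymptote`,
#'   `mod_rate`, `mod_midpoint`, `unmet_alpha`, `unmet_beta`. Defaults are
#'   the generator defaults of [fp_hyperparams()].
#' @param sd_region,sd_division hierarchical dispersion of the transformed
#'   area parameters (logit asymptote, log rate, midpoint, per curve, plus
#'   unmet intercept), length 7.
#' @param rho_range support of the uniform prior on the AR(1)
#'   autocorrelation (within (-1, 1)).
#' @param sigma_scale half-normal prior scales for the three AR(1)
#'   innovation SDs (total, modern share, unmet ratio).
#' @param kappa_meanlog,kappa_sdlog lognormal prior on `kappa - 1`, the
#'   excess variance inflation of non-DHS (MICS) observations.
#' @param fix optional named list pinning global parameters (`rho`,
#'   `sigma_cpr`, `sigma_mod`, `sigma_unmet`, `kappa`) to constants.
#' @param fix_area character vector of transformed area-parameter names
#'   (see `fpemsub:::theta_names`) to fix at the country values for every
#'   area (used e.g. to reduce the model for oracle checks).
#' @param rhat_threshold potential-scale-reduction threshold above which a
#'   convergence warning is raised.
#' @return list of class `fpem_config`.
#' @export
fpem_config <- function(years = 1990:2030, chains = 4, warmup = 1000,
                        draws = 1000, thin = 1, seed,
                        country_params = NULL,
                        sd_region = c(0.30, 0.15, 3.0, 0.30, 0.15, 3.0, 0.20),
                        sd_division = c(0.20, 0.10, 2.0, 0.20, 0.10, 2.0, 0.15),
                        rho_range = c(0, 0.95),
                        sigma_scale = c(cpr = 0.1, mod = 0.1, unmet = 0.15),
                        kappa_meanlog = log(1.25), kappa_sdlog = 0.75,
                        fix = list(), fix_area = character(),
                        rhat_threshold = 1.05) {
  assert_that(is_count(chains) && chains >= 2, "chains must be >= 2")
  assert_that(is_count(draws), "draws must be >= 1")
  assert_that(is_count(warmup + 1), "warmup must be a non-negative integer")
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1,
              "a scalar seed is required")
  assert_that(rho_range[1] >= -1 + 1e-9 && rho_range[2] <= 1 - 1e-9 &&
                rho_range[1] < rho_range[2],
              "rho prior support must lie within (-1, 1)")
  assert_that(length(sd_region) == 7 && length(sd_division) == 7,
              "dispersion vectors must have length 7")
  assert_that(all(fix_area %in% theta_names),
              "fix_area must name transformed area parameters")
  if (is.null(country_params)) {
    hp <- fp_hyperparams()
    country_params <- hp[c("cpr_asymptote", "cpr_rate", "cpr_midpoint",
                           "mod_asymptote", "mod_rate", "mod_midpoint",
                           "unmet_alpha", "unmet_beta")]
  }
  assert_that(is_count(thin), "thin must be a positive integer")
  structure(list(years = years, chains = chains, warmup = warmup,
                 draws = draws, thin = thin, seed = as.integer(seed),
                 country_params = country_params,
                 sd_region = sd_region, sd_division = sd_division,
                 rho_range = rho_range, sigma_scale = unname(sigma_scale),
                 kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
                 fix = fix, fix_area = fix_area,
                 rhat_threshold = rhat_threshold),
            class = "fpem_config")
}

# ---- observation preprocessing -------------------------------------------

component_se <- function(obs, comp, p) {
  se_col <- paste0(comp, "_se")
  if (se_col %in% names(obs) && !all(is.na(obs[[se_col]]))) {
    se <- obs[[se_col]]
  } else {
    se <- rep(NA_real_, nrow(obs))
  }
  miss <- is.na(se)
  se[miss] <- sqrt(p[miss] * (1 - p[miss]) / obs$n_eff[miss])
  se
}

# Transform survey rows into logit-scale observation sets per area and
# process ("c" total prevalence, "r" modern share, "u" unmet/non-use).
prep_observations <- function(obs, hierarchy, years) {
  need <- c("area_id", "year", "source_type")
  assert_that(all(need %in% names(obs)),
              "observations must have columns %s", paste(need, collapse = ", "))
  assert_that(all(obs$area_id %in% area_ids(hierarchy)),
              "observations contain area ids missing from the hierarchy")
  assert_that(all(obs$year %in% years),
              "observations contain years outside the estimation grid")
  assert_that(all(obs$source_type %in% c("DHS", "MICS")),
              "source_type must be DHS or MICS")
  if (!"n_eff" %in% names(obs)) obs$n_eff <- NA_real_
  comps <- c("cpr_total", "mcpr", "traditional", "unmet_any")
  for (q in comps) if (!q %in% names(obs)) obs[[q]] <- NA_real_
  reported <- !is.na(obs[, comps, drop = FALSE])
  assert_that(all(rowSums(reported) >= 1),
              "every observation must report at least one component")
  pr <- obs[, comps, drop = FALSE]
  bad <- !is.na(pr) & (pr < 0 | pr > 1)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    fp_stop("observation row %d: %s = %g is outside [0, 1]",
            ij[1], comps[ij[2]], pr[ij[1], ij[2]])
  }

  ne <- ifelse(is.na(obs$n_eff), 1e4, obs$n_eff)
  c_obs <- ifelse(is.na(obs$cpr_total), NA,
                  pmin(pmax(obs$cpr_total, 0.5 / ne), 1 - 0.5 / ne))
  m_obs <- ifelse(is.na(obs$mcpr), NA,
                  pmin(pmax(obs$mcpr, 0.5 / ne), 1 - 0.5 / ne))
  t_obs <- ifelse(is.na(obs$traditional), NA,
                  pmin(pmax(obs$traditional, 0.5 / ne), 1 - 0.5 / ne))
  u_obs <- ifelse(is.na(obs$unmet_any), NA,
                  pmin(pmax(obs$unmet_any, 0.5 / ne), 1 - 0.5 / ne))

  # derive a usable total for ratio terms
  total <- ifelse(!is.na(c_obs), c_obs,
                  ifelse(!is.na(m_obs) & !is.na(t_obs),
                         pmin(m_obs + t_obs, 1 - 0.5 / ne), NA))
  se_c <- component_se(obs, "cpr_total", c_obs)
  se_m <- component_se(obs, "mcpr", m_obs)
  se_u <- component_se(obs, "unmet_any", u_obs)

  if (any(!is.na(m_obs) & is.na(total))) {
    fp_stop("row %d reports mcpr without cpr_total or traditional; the modern share cannot be formed",
            which(!is.na(m_obs) & is.na(total))[1])
  }
  if (any(!is.na(u_obs) & is.na(total))) {
    fp_stop("row %d reports unmet_any without a usable total prevalence",
            which(!is.na(u_obs) & is.na(total))[1])
  }

  mics <- obs$source_type == "MICS"
  yidx <- match(obs$year, years)
  eps <- 1e-4
  sets <- list()
  for (a in unique(obs$area_id)) {
    ia <- which(obs$area_id == a)
    o <- list()
    keep <- ia[!is.na(c_obs[ia])]
    if (length(keep)) {
      p <- c_obs[keep]
      o$c <- list(idx = yidx[keep], y = logit(p),
                  v = (se_c[keep] / (p * (1 - p)))^2, mics = mics[keep])
    }
    keep <- ia[!is.na(m_obs[ia]) & !is.na(total[ia])]
    if (length(keep)) {
      s <- pmin(pmax(m_obs[keep] / total[keep], eps), 1 - eps)
      vs <- (se_m[keep]^2 / total[keep]^2 +
               se_c[keep]^2 * m_obs[keep]^2 / total[keep]^4) /
        (s * (1 - s))^2
      o$r <- list(idx = yidx[keep], y = logit(s), v = vs, mics = mics[keep])
    }
    keep <- ia[!is.na(u_obs[ia]) & !is.na(total[ia])]
    if (length(keep)) {
      z <- pmin(pmax(u_obs[keep] / (1 - total[keep]), eps), 1 - eps)
      vz <- (se_u[keep]^2 / (1 - total[keep])^2 +
               se_c[keep]^2 * u_obs[keep]^2 / (1 - total[keep])^4) /
        (z * (1 - z))^2
      o$u <- list(idx = yidx[keep], y = logit(z), v = vz, mics = mics[keep])
    }
    sets[[a]] <- o
  }
  sets
}

# ---- likelihood -----------------------------------------------------------

ldmvnorm_chol <- function(r, S) {
  U <- chol(S)
  w <- backsolve(U, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + sum(w * w)) - sum(log(diag(U)))
}

mu_process <- function(proc, theta, years_at, beta) {
  if (proc == "c") {
    Lc <- invlogit(theta[1]) * invlogit(exp(theta[2]) * (years_at - theta[3]))
    logit(Lc)
  } else if (proc == "r") {
    Lr <- invlogit(theta[4]) * invlogit(exp(theta[5]) * (years_at - theta[6]))
    logit(Lr)
  } else {
    Lc <- invlogit(theta[1]) * invlogit(exp(theta[2]) * (years_at - theta[3]))
    theta[7] + beta * Lc
  }
}

proc_sigma <- function(proc, glob) {
  switch(proc, c = glob$sigma_cpr, r = glob$sigma_mod, u = glob$sigma_unmet)
}

loglik_area <- function(theta, oset, glob, years, beta) {
  ll <- 0
  for (proc in names(oset)) {
    o <- oset[[proc]]
    mu <- mu_process(proc, theta, years[o$idx], beta)
    S <- ar1_cov(glob$rho, proc_sigma(proc, glob), o$idx) +
      diag(o$v * ifelse(o$mics, glob$kappa, 1), length(o$y))
    ll <- ll + ldmvnorm_chol(o$y - mu, S)
  }
  ll
}

# The observation covariance depends only on the global parameters, so its
# Cholesky factor is cached across the (far more frequent) area updates.
build_cov_cache <- function(osets, glob) {
  lapply(osets, function(oset) {
    lapply(stats::setNames(names(oset), names(oset)), function(proc) {
      o <- oset[[proc]]
      S <- ar1_cov(glob$rho, proc_sigma(proc, glob), o$idx) +
        diag(o$v * ifelse(o$mics, glob$kappa, 1), length(o$y))
      U <- chol(S)
      list(U = U, logdet = sum(log(diag(U))),
           const = -0.5 * length(o$y) * log(2 * pi))
    })
  })
}

loglik_area_cached <- function(theta, oset, cache_a, years, beta) {
  ll <- 0
  for (proc in names(oset)) {
    o <- oset[[proc]]
    ca <- cache_a[[proc]]
    r <- o$y - mu_process(proc, theta, years[o$idx], beta)
    w <- backsolve(ca$U, r, transpose = TRUE)
    ll <- ll + ca$const - ca$logdet - 0.5 * sum(w * w)
  }
  ll
}

# ---- global parameter transform ------------------------------------------

glob_from_psi <- function(psi, fix, rho_range) {
  g <- list()
  g$rho <- fix$rho %||%
    (rho_range[1] + diff(rho_range) * invlogit(psi[["t_rho"]]))
  g$sigma_cpr <- fix$sigma_cpr %||% exp(psi[["ls_c"]])
  g$sigma_mod <- fix$sigma_mod %||% exp(psi[["ls_r"]])
  g$sigma_unmet <- fix$sigma_unmet %||% exp(psi[["ls_u"]])
  g$kappa <- fix$kappa %||% (1 + exp(psi[["g_kappa"]]))
  g
}

logprior_psi <- function(psi, cfg) {
  lp <- 0
  if ("t_rho" %in% names(psi)) {
    p <- invlogit(psi[["t_rho"]])
    lp <- lp + log(diff(cfg$rho_range)) + log(p) + log1p(-p)
  }
  sc <- cfg$sigma_scale
  for (i in seq_along(c("ls_c", "ls_r", "ls_u"))) {
    nm <- c("ls_c", "ls_r", "ls_u")[i]
    if (nm %in% names(psi)) {
      s <- exp(psi[[nm]])
      lp <- lp + stats::dnorm(s, 0, sc[i], log = TRUE) + psi[[nm]]
    }
  }
  if ("g_kappa" %in% names(psi)) {
    lp <- lp + stats::dnorm(psi[["g_kappa"]], cfg$kappa_meanlog,
                            cfg$kappa_sdlog, log = TRUE)
  }
  lp
}

# ---- split R-hat ----------------------------------------------------------

split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-12) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# ---- main fitting function ------------------------------------------------

#' Fit the subnational family-planning estimation model
#'
#' Bayesian estimation and projection of total contraceptive prevalence,
#' modern-method prevalence (mCPR), traditional use, unmet need and derived
#' quantities for every area and year of the configured grid. Division
#' parameters are pooled toward their region's, regions toward fixed
#' country values. The likelihood acts on logit-transformed survey
#' components with per-observation sampling variance, inflated by an
#' estimated factor for non-DHS sources.
#'
#' @param observations survey observation table (see [read_surveys()] for
#'   the schema): columns `area_id`, `year`, `source_type`, `n_eff` and/or
#'   `*_se` columns, plus any of `cpr_total`, `mcpr`, `traditional`,
#'   `unmet_any` (missing components as `NA`).
#' @param hierarchy an [make_hierarchy()] object.
#' @param populations optional MWRA counts (`area_id`, `year`, `mwra`);
#'   stored for downstream count-based indicators.
#' @param config an [fpem_config()]; its `seed` drives all randomness.
#' @return object of class `fpem_fit` with elements `posterior` (sample x
#'   area x year x quantity array), `diagnostics` (split R-hat per
#'   monitored parameter), `param_draws`, `config`, `hierarchy`,
#'   `populations`, `observations`.
#' @seealso [summary.fpem_fit()], [predict.fpem_fit()], [coef.fpem_fit()]
#' @export
fpem_fit <- function(observations, hierarchy, populations = NULL, config) {
  validate_hierarchy(hierarchy)
  assert_that(inherits(config, "fpem_config"), "config must be an fpem_config")
  years <- config$years
  ny <- length(years)
  h <- as.data.frame(hierarchy)
  ids <- h$area_id
  level <- stats::setNames(h$level, ids)
  parent <- stats::setNames(h$parent_id, ids)

  osets <- prep_observations(observations, hierarchy, years)
  no_data <- setdiff(ids, names(osets))
  if (length(no_data)) {
    warning("areas without observations (prior-driven estimates): ",
            paste(no_data, collapse = ", "), call. = FALSE)
  }

  cp <- config$country_params
  theta0 <- c(logit(cp$cpr_asymptote), log(cp$cpr_rate), cp$cpr_midpoint,
              logit(cp$mod_asymptote), log(cp$mod_rate), cp$mod_midpoint,
              cp$unmet_alpha)
  names(theta0) <- theta_names
  beta <- cp$unmet_beta
  free_theta <- setdiff(theta_names, config$fix_area)
  fi <- match(free_theta, theta_names)

  psi_names <- c("t_rho", "ls_c", "ls_r", "ls_u", "g_kappa")
  fixed_glob <- c(rho = "t_rho", sigma_cpr = "ls_c", sigma_mod = "ls_r",
                  sigma_unmet = "ls_u", kappa = "g_kappa")
  psi_free <- setdiff(psi_names, fixed_glob[names(config$fix)])
  psi0 <- c(t_rho = 0, ls_c = log(0.05), ls_r = log(0.05),
            ls_u = log(0.08), g_kappa = config$kappa_meanlog)[psi_free]

  sd_for <- function(a) {
    if (level[a] == "region") config$sd_region else config$sd_division
  }
  sub_ids <- ids[level != "country"]
  region_ids <- ids[level == "region"]

  thin <- config$thin %||% 1L
  n_iter <- config$warmup + config$draws * thin
  chains <- config$chains
  n_keep <- config$draws

  # per-chain storage for monitored parameters and posterior draws
  mon_names <- c(unlist(lapply(sub_ids, function(a)
    paste0(a, ".", free_theta))), psi_free)
  mon_array <- array(NA_real_, c(n_keep, chains, length(mon_names)),
                     dimnames = list(NULL, NULL, mon_names))
  theta_draws <- array(NA_real_, c(n_keep, chains, length(ids), 7),
                       dimnames = list(NULL, NULL, ids, theta_names))
  glob_draws <- array(NA_real_, c(n_keep, chains, 5),
                      dimnames = list(NULL, NULL,
                                      c("rho", "sigma_cpr", "sigma_mod",
                                        "sigma_unmet", "kappa")))
  accept <- numeric(0)

  for (ch in seq_len(chains)) {
    set.seed(config$seed + ch * 1000L)
    theta <- matrix(rep(theta0, each = length(ids)), nrow = length(ids),
                    dimnames = list(ids, theta_names))
    for (a in sub_ids) {
      par0 <- if (level[a] == "region") theta0 else theta[parent[a], ]
      theta[a, fi] <- par0[fi] + 0.1 * sd_for(a)[fi] * stats::rnorm(length(fi))
    }
    psi <- psi0 + 0.05 * stats::rnorm(length(psi0))
    names(psi) <- psi_free
    glob <- glob_from_psi(psi, config$fix, config$rho_range)

    cache <- build_cov_cache(osets, glob)
    lik <- stats::setNames(numeric(length(ids)), ids)
    for (a in ids) {
      lik[a] <- if (!is.null(osets[[a]])) {
        loglik_area_cached(theta[a, ], osets[[a]], cache[[a]], years, beta)
      } else 0
    }

    # adaptive proposal state: per-block scalar scale (Robbins-Monro toward
    # 0.234 acceptance) and full empirical covariance (Haario-style), which
    # handles the strong ridges between asymptote, rate and midpoint
    ls_block <- stats::setNames(rep(log(0.5), length(sub_ids) + 1),
                                c(sub_ids, ".glob"))
    ls_branch <- stats::setNames(rep(log(0.3), length(region_ids)),
                                 region_ids)
    run_m <- list(); run_C <- list(); prop_L <- list(); C0 <- list()
    for (a in sub_ids) {
      run_m[[a]] <- theta[a, fi]
      C0[[a]] <- diag((0.3 * sd_for(a)[fi])^2, length(fi))
      run_C[[a]] <- C0[[a]]
      prop_L[[a]] <- t(chol(run_C[[a]]))
    }
    run_m[[".glob"]] <- psi
    C0[[".glob"]] <- diag(0.04, length(psi))
    run_C[[".glob"]] <- C0[[".glob"]]
    prop_L[[".glob"]] <- if (length(psi)) t(chol(run_C[[".glob"]])) else NULL
    acc_cnt <- 0; acc_tot <- 0

    for (it in seq_len(n_iter)) {
      adapt <- it <= config$warmup
      # slow adaptation rates: scale via Robbins-Monro, covariance via a
      # decaying running estimate with a floor toward the initial shape
      gam_s <- if (adapt) min(0.1, 2 / it^0.6) else 0
      gam <- if (adapt) 1 / (20 + it) else 0

      for (a in sub_ids) {
        th_new <- theta[a, ]
        th_new[fi] <- theta[a, fi] + exp(ls_block[a]) *
          as.numeric(prop_L[[a]] %*% stats::rnorm(length(fi)))
        par_mean <- if (level[a] == "region") theta0 else theta[parent[a], ]
        sda <- sd_for(a)
        lp_old <- sum(stats::dnorm(theta[a, fi], par_mean[fi], sda[fi],
                                   log = TRUE))
        lp_new <- sum(stats::dnorm(th_new[fi], par_mean[fi], sda[fi],
                                   log = TRUE))
        if (level[a] == "region") {
          kids <- ids[!is.na(parent) & parent == a]
          for (k in kids) {
            sdk <- config$sd_division
            lp_old <- lp_old + sum(stats::dnorm(theta[k, fi], theta[a, fi],
                                                sdk[fi], log = TRUE))
            lp_new <- lp_new + sum(stats::dnorm(theta[k, fi], th_new[fi],
                                                sdk[fi], log = TRUE))
          }
        }
        ll_new <- if (!is.null(osets[[a]])) {
          loglik_area_cached(th_new, osets[[a]], cache[[a]], years, beta)
        } else 0
        lacc <- (ll_new + lp_new) - (lik[a] + lp_old)
        ok <- is.finite(lacc) && log(stats::runif(1)) < lacc
        if (ok) { theta[a, ] <- th_new; lik[a] <- ll_new }
        if (adapt) {
          ls_block[a] <- ls_block[a] + gam_s * ((if (ok) 1 else 0) - 0.234)
          d <- theta[a, fi] - run_m[[a]]
          run_m[[a]] <- run_m[[a]] + gam * d
          run_C[[a]] <- (1 - gam) * run_C[[a]] + gam * tcrossprod(d)
          if (it %% 25 == 0) {
            prop_L[[a]] <- t(chol(run_C[[a]] + 0.05 * C0[[a]]))
          }
        }
      }

      # branch translation: shift a region and all its divisions jointly,
      # the slow direction of the hierarchical posterior (children priors
      # are unchanged because relative offsets are preserved)
      for (r in region_ids) {
        branch <- c(r, ids[!is.na(parent) & parent == r])
        delta <- exp(ls_branch[r]) * config$sd_region[fi] *
          stats::rnorm(length(fi))
        lp_old <- sum(stats::dnorm(theta[r, fi], theta0[fi],
                                   config$sd_region[fi], log = TRUE))
        lp_new <- sum(stats::dnorm(theta[r, fi] + delta, theta0[fi],
                                   config$sd_region[fi], log = TRUE))
        ll_old <- sum(lik[branch])
        ll_new <- 0
        th_br <- list()
        for (b in branch) {
          tb <- theta[b, ]
          tb[fi] <- tb[fi] + delta
          th_br[[b]] <- tb
          ll_new <- ll_new + if (!is.null(osets[[b]])) {
            loglik_area_cached(tb, osets[[b]], cache[[b]], years, beta)
          } else 0
        }
        lacc <- (ll_new + lp_new) - (ll_old + lp_old)
        ok <- is.finite(lacc) && log(stats::runif(1)) < lacc
        if (ok) {
          for (b in branch) {
            theta[b, ] <- th_br[[b]]
            lik[b] <- if (!is.null(osets[[b]])) {
              loglik_area_cached(th_br[[b]], osets[[b]], cache[[b]],
                                 years, beta)
            } else 0
          }
        }
        if (adapt) {
          ls_branch[r] <- ls_branch[r] + gam_s * ((if (ok) 1 else 0) - 0.234)
        }
      }

      if (length(psi)) {
        psi_new <- psi + exp(ls_block[".glob"]) *
          as.numeric(prop_L[[".glob"]] %*% stats::rnorm(length(psi)))
        names(psi_new) <- psi_free
        glob_new <- glob_from_psi(psi_new, config$fix, config$rho_range)
        cache_new <- build_cov_cache(osets, glob_new)
        lik_new <- lik
        for (a in names(osets)) {
          lik_new[a] <- loglik_area_cached(theta[a, ], osets[[a]],
                                           cache_new[[a]], years, beta)
        }
        lacc <- (sum(lik_new) + logprior_psi(psi_new, config)) -
          (sum(lik) + logprior_psi(psi, config))
        ok <- is.finite(lacc) && log(stats::runif(1)) < lacc
        if (ok) { psi <- psi_new; glob <- glob_new; lik <- lik_new
                  cache <- cache_new }
        acc_tot <- acc_tot + 1; if (ok) acc_cnt <- acc_cnt + 1
        if (adapt) {
          ls_block[".glob"] <- ls_block[".glob"] +
            gam_s * ((if (ok) 1 else 0) - 0.234)
          d <- psi - run_m[[".glob"]]
          run_m[[".glob"]] <- run_m[[".glob"]] + gam * d
          run_C[[".glob"]] <- (1 - gam) * run_C[[".glob"]] + gam * tcrossprod(d)
          if (it %% 25 == 0) {
            prop_L[[".glob"]] <- t(chol(run_C[[".glob"]] +
                                          0.05 * C0[[".glob"]]))
          }
        }
      }

      if (it > config$warmup && (it - config$warmup) %% thin == 0) {
        k <- (it - config$warmup) %/% thin
        if (length(sub_ids)) {
          mon_array[k, ch, seq_len(length(sub_ids) * length(fi))] <-
            as.numeric(t(theta[sub_ids, fi, drop = FALSE]))
        }
        if (length(psi)) {
          mon_array[k, ch, length(sub_ids) * length(fi) + seq_along(psi)] <- psi
        }
        theta_draws[k, ch, , ] <- theta
        glob_draws[k, ch, ] <- c(glob$rho, glob$sigma_cpr, glob$sigma_mod,
                                 glob$sigma_unmet, glob$kappa)
      }
    }
    accept[ch] <- if (acc_tot) acc_cnt / acc_tot else NA_real_
  }

  rhat <- vapply(seq_along(mon_names), function(j)
    split_rhat(mon_array[, , j, drop = TRUE]), numeric(1))
  diagnostics <- data.frame(parameter = mon_names, rhat = rhat)
  if (any(is.finite(rhat) & rhat > config$rhat_threshold)) {
    warning(sprintf(
      "convergence: %d parameter(s) exceed the R-hat threshold %.2f (max %.3f)",
      sum(rhat > config$rhat_threshold, na.rm = TRUE),
      config$rhat_threshold, max(rhat, na.rm = TRUE)), call. = FALSE)
  }

  posterior <- build_trajectories(theta_draws, glob_draws, osets, ids,
                                  years, beta, config)

  structure(list(posterior = posterior, diagnostics = diagnostics,
                 param_draws = list(theta = theta_draws, glob = glob_draws),
                 acceptance = accept, config = config,
                 hierarchy = hierarchy, populations = populations,
                 observations = observations, no_data_areas = no_data),
            class = "fpem_fit")
}

# Reconstruct posterior trajectories by conditional simulation of the AR(1)
# distortions given each retained parameter draw.
build_trajectories <- function(theta_draws, glob_draws, osets, ids, years,
                               beta, config) {
  ny <- length(years)
  n_keep <- dim(theta_draws)[1]
  chains <- dim(theta_draws)[2]
  S <- n_keep * chains
  post <- array(NA_real_, c(S, length(ids), ny, length(fp_quantities)),
                dimnames = list(NULL, ids, years, fp_quantities))
  set.seed(config$seed + 777L)
  grid_idx <- seq_len(ny)
  s <- 0
  for (ch in seq_len(chains)) for (k in seq_len(n_keep)) {
    s <- s + 1
    glob <- list(rho = glob_draws[k, ch, "rho"],
                 sigma_cpr = glob_draws[k, ch, "sigma_cpr"],
                 sigma_mod = glob_draws[k, ch, "sigma_mod"],
                 sigma_unmet = glob_draws[k, ch, "sigma_unmet"],
                 kappa = glob_draws[k, ch, "kappa"])
    for (ai in seq_along(ids)) {
      a <- ids[ai]
      theta <- theta_draws[k, ch, ai, ]
      eps <- list()
      for (proc in c("c", "r", "u")) {
        sig <- proc_sigma(proc, glob)
        if (sig == 0) { eps[[proc]] <- numeric(ny); next }
        K <- ar1_cov(glob$rho, sig, grid_idx)
        o <- osets[[a]][[proc]]
        if (is.null(o)) {
          eps[[proc]] <- as.numeric(t(chol(K + diag(1e-10, ny))) %*%
                                      stats::rnorm(ny))
        } else {
          mu_o <- mu_process(proc, theta, years[o$idx], beta)
          Soo <- K[o$idx, o$idx, drop = FALSE] +
            diag(o$v * ifelse(o$mics, glob$kappa, 1), length(o$y))
          A <- K[, o$idx, drop = FALSE] %*% solve(Soo)
          m <- as.numeric(A %*% (o$y - mu_o))
          V <- K - A %*% K[o$idx, , drop = FALSE]
          V <- (V + t(V)) / 2
          eps[[proc]] <- m + as.numeric(t(chol(V + diag(1e-9, ny))) %*%
                                          stats::rnorm(ny))
        }
      }
      tr <- area_trajectory(stats::setNames(theta, theta_names), years,
                            beta, eps$c, eps$r, eps$u)
      um <- tr$unmet_any + tr$traditional
      dm <- tr$mcpr + um
      ds <- ifelse(dm > 0, tr$mcpr / dm, 0)
      post[s, ai, , ] <- cbind(tr$cpr_total, tr$mcpr, tr$traditional,
                               tr$unmet_any, um, dm, ds)
    }
  }
  post
}
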