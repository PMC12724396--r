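#' Heat-attributable numbers for one curve and series slice
#'
#' For every day of the slice hotter than the threshold percentile of
#' the location's full-period warm-season distribution, the daily
#' attributable fraction is `(RR - 1)/RR = 1 - exp(-logRR)` with `RR`
#' from the (MMT-centered) overall cumulative curve, floored at 0 by
#' default; attributable numbers are `deaths * AF`.  The
#' heat-attributable fraction (HAF) expresses their sum as a percentage
#' of all warm-season deaths in the slice.
#'
#' @param series data.frame slice with `date`, `tmean`, `deaths`.
#' @param curve a centered `"reduced_curve"` on the percentile scale.
#' @param table the location's percentile table ([pct_table()]).
#' @param threshold_pct attribution threshold percentile (default 95).
#' @param floor_af floor negative daily fractions at 0 (default TRUE).
#' @param season warm-season months.
#'
#' @return List with `an_total`, `deaths_total`, `haf` (%), and the
#'   per-day table `days` (`date`, `af`, `an`).
#' @export
attributable_numbers <- function(series, curve, table,
                                 threshold_pct = 95, floor_af = TRUE,
                                 season = SEASON_MONTHS) {
  stopifnot(inherits(curve, "reduced_curve"))
  if (is.null(curve$cen)) stop("curve must be centered at its MMT")
  seas <- in_season(series$date, season)
  pct <- to_percentile(series$tmean, table)
  hot <- seas & pct > threshold_pct
  logrr <- predict(curve, pct[hot])$logrr
  af <- 1 - exp(-logrr)
  if (floor_af) af <- pmax(af, 0)
  an <- series$deaths[hot] * af
  deaths_total <- sum(series$deaths[seas])
  list(an_total = sum(an), deaths_total = deaths_total,
       haf = if (deaths_total > 0) 100 * sum(an) / deaths_total else 0,
       days = data.frame(date = series$date[hot], af = af, an = an))
}

#' Annual heat-attributable death rate per 100 000
#'
#' @param an_total attributable deaths over the period.
#' @param population reference population (> 0).
#' @param n_years number of years the total covers (> 0).
#' @return Annual attributable deaths per 100 000 inhabitants.
#' @export
had_rate <- function(an_total, population, n_years) {
  if (any(population <= 0)) stop("'population' must be > 0")
  if (any(n_years <= 0)) stop("'n_years' must be > 0")
  an_total / n_years / population * 1e5
}

# precompute per-unit attribution inputs: hot-day exposure basis rows,
# deaths, person-years, and the shared MMT search grid basis
attribution_units <- function(dataset, cohort, config) {
  vs <- dataset$var_spec
  grid <- seq(config$mmt_range[1L], config$mmt_range[2L],
              by = config$mmt_step)
  gbasis <- bspline_basis(grid, vs)
  units <- vector("list", nrow(dataset$covs))
  for (city_id in unique(dataset$covs$city)) {
    ser <- cohort$series[[city_id]]
    if (is.null(ser)) stop("city absent from cohort: ", city_id)
    tab <- dataset$city_tables[[city_id]]
    pct <- to_percentile(ser$tmean, tab)
    sp <- split_subperiods(ser, config)
    spi <- vapply(sp, `[[`, 0L, "index")
    rows_u <- which(dataset$covs$city == city_id)
    for (u in rows_u) {
      s <- sp[[match(dataset$covs$subperiod[u], spi)]]
      r <- s$outcome_rows
      hot <- r[pct[r] > config$threshold_pct]
      units[[u]] <- list(
        bhot = bspline_basis(pct[hot], vs),
        deaths_hot = ser$deaths[hot],
        deaths_total = sum(ser$deaths[r]),
        person_years = dataset$covs$population[u] * s$n_years)
    }
  }
  list(units = units, grid = grid, gbasis = gbasis)
}

# attributable numbers for every unit given a n x p coefficient matrix;
# each unit's curve is centered at its own grid-searched MMT
an_by_unit <- function(coefs, au, floor_af = TRUE, unit_idx = NULL) {
  if (is.null(unit_idx)) unit_idx <- seq_len(nrow(coefs))
  gv <- au$gbasis %*% t(coefs[unit_idx, , drop = FALSE])
  mmt_i <- apply(gv, 2L, which.min)
  an <- numeric(length(unit_idx))
  for (k in seq_along(unit_idx)) {
    u <- au$units[[unit_idx[k]]]
    if (!length(u$deaths_hot)) next
    logrr <- drop(u$bhot %*% coefs[unit_idx[k], ]) - gv[mmt_i[k], k]
    af <- 1 - exp(-logrr)
    if (floor_af) af <- pmax(af, 0)
    an[k] <- sum(u$deaths_hot * af)
  }
  an
}

# pooled summaries per aggregation scope for one coefficient sample
aggregate_attribution <- function(an_f, an_cf, covs, au, post,
                                  weighting = "pooled") {
  deaths <- vapply(au$units, `[[`, 0, "deaths_total")
  py <- vapply(au$units, `[[`, 0, "person_years")
  keys <- unique(rbind(
    data.frame(scope_type = "location", scope = covs$city,
               stringsAsFactors = FALSE)[post, ],
    data.frame(scope_type = "country", scope = covs$country,
               stringsAsFactors = FALSE)[post, ],
    data.frame(scope_type = "region", scope = as.character(covs$region),
               stringsAsFactors = FALSE)[post, ],
    data.frame(scope_type = "hppclass",
               scope = paste0("class", covs$hppclass),
               stringsAsFactors = FALSE)[post, ],
    data.frame(scope_type = "overall", scope = "overall",
               stringsAsFactors = FALSE)))
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    sel <- switch(keys$scope_type[i],
      location = post & covs$city == keys$scope[i],
      country = post & covs$country == keys$scope[i],
      region = post & as.character(covs$region) == keys$scope[i],
      hppclass = post & paste0("class", covs$hppclass) == keys$scope[i],
      overall = post)
    haf_f <- 100 * sum(an_f[sel]) / sum(deaths[sel])
    haf_cf <- 100 * sum(an_cf[sel]) / sum(deaths[sel])
    out <- rbind(out, data.frame(
      scope_type = keys$scope_type[i], scope = keys$scope[i],
      haf_factual = haf_f, haf_counterfactual = haf_cf,
      haf_change = if (haf_cf != 0) (haf_f - haf_cf) / haf_cf * 100
                   else 0,
      had_factual = sum(an_f[sel]) / sum(py[sel]) * 1e5,
      had_counterfactual = sum(an_cf[sel]) / sum(py[sel]) * 1e5,
      had_difference = (sum(an_f[sel]) - sum(an_cf[sel])) /
        sum(py[sel]) * 1e5,
      an_factual = sum(an_f[sel]), an_counterfactual = sum(an_cf[sel]),
      deaths_avoided = sum(an_cf[sel]) - sum(an_f[sel]),
      stringsAsFactors = FALSE))
  }
  if (weighting == "unweighted") {
    cn <- out$scope_type == "country"
    creg <- covs$region[match(out$scope[cn], covs$country)]
    for (j in c("haf_change", "had_difference")) {
      for (rg in unique(as.character(creg))) {
        out[out$scope_type == "region" & out$scope == rg, j] <-
          mean(out[cn, j][as.character(creg) == rg])
      }
      out[out$scope_type == "overall", j] <- mean(out[cn, j])
    }
  }
  out
}

#' Factual vs counterfactual heat attribution with Monte-Carlo CIs
#'
#' Computes BLUP scenario curves for every city-subperiod (factual: HPP
#' indicator as observed; counterfactual: indicator forced to 0),
#' converts them to attributable numbers on days above the threshold
#' percentile of the post-implementation subperiods, aggregates to
#' location, country, region, HPP-class and overall scopes, and derives
#' 95% empirical confidence intervals by sampling the fixed-effect
#' coefficients from their multivariate normal distribution
#' (`n_samples` draws; random effects held at their estimates unless
#' `config$sample_random_effects`).
#'
#' @param model fitted `"meta_model"`.
#' @param dataset the `"meta_dataset"` it was fitted on.
#' @param cohort the cohort holding the daily series.
#' @param config a [run_config()].
#' @param n_samples Monte-Carlo samples (default from config).
#' @param seed RNG seed (default from config).
#'
#' @return Object of class `"attribution_result"`: list with `table`
#'   (per-scope estimates with CI columns), `units` (per-unit point
#'   estimates), `trajectories` (per-subperiod overall HAF under both
#'   scenarios), `deaths_avoided` (point + CI) and `n_samples`.
#' @export
monte_carlo_attribution <- function(model, dataset, cohort,
                                    config = dataset$config,
                                    n_samples = config$n_samples,
                                    seed = config$seed) {
  stopifnot(inherits(model, "meta_model"))
  if (n_samples < 100L)
    warning("fewer than 100 Monte-Carlo samples; CIs will be unstable")
  if (!is_psd(model$vcov_beta, tol = 1e-6 * max(abs(model$vcov_beta))))
    stop("fixed-effect covariance is not PSD")
  covs <- dataset$covs
  post <- covs$hpp == 1
  if (!any(post)) stop("no post-implementation units")
  au <- attribution_units(dataset, cohort, config)
  covs_cf <- covs
  covs_cf$hpp <- 0

  mm_f <- meta_design_rows(model, covs)
  mm_cf <- meta_design_rows(model, covs_cf)
  pred_obs <- blup(model, dataset)
  ran_part <- pred_obs - mm_f %*% t(model$beta_mat)

  unit_coefs <- function(bm, mm) mm %*% t(bm) + ran_part

  point <- list(f = unit_coefs(model$beta_mat, mm_f),
                cf = unit_coefs(model$beta_mat, mm_cf))
  an_f0 <- an_by_unit(point$f, au, config$floor_af)
  an_cf0 <- an_by_unit(point$cf, au, config$floor_af)
  tab0 <- aggregate_attribution(an_f0, an_cf0, covs, au, post,
                                config$region_mean_weighting)

  set.seed(seed)
  betas <- MASS::mvrnorm(n_samples, model$beta, model$vcov_beta)
  ran_draw <- NULL
  if (isTRUE(config$sample_random_effects))
    ran_draw <- raneff_sampler(model, dataset)
  samp <- vector("list", n_samples)
  traj_samp <- vector("list", n_samples)
  deaths <- vapply(au$units, `[[`, 0, "deaths_total")
  for (s in seq_len(n_samples)) {
    bm <- matrix(betas[s, ], nrow = model$p)
    rp <- if (is.null(ran_draw)) ran_part else ran_draw()
    cf_s <- mm_f %*% t(bm) + rp
    cc_s <- mm_cf %*% t(bm) + rp
    af <- an_by_unit(cf_s, au, config$floor_af)
    ac <- an_by_unit(cc_s, au, config$floor_af)
    samp[[s]] <- aggregate_attribution(af, ac, covs, au, post,
                                       config$region_mean_weighting)
    traj_samp[[s]] <- vapply(
      sort(unique(covs$subperiod)),
      function(k) {
        sel <- covs$subperiod == k
        c(100 * sum(af[sel]) / sum(deaths[sel]),
          100 * sum(ac[sel]) / sum(deaths[sel]))
      }, numeric(2L))
  }

  ci_cols <- c("haf_factual", "haf_counterfactual", "haf_change",
               "had_factual", "had_counterfactual", "had_difference",
               "deaths_avoided")
  tab <- tab0
  for (col in ci_cols) {
    vals <- vapply(samp, function(d) d[[col]], numeric(nrow(tab0)))
    vals <- matrix(vals, nrow = nrow(tab0))
    tab[[paste0(col, "_lo")]] <-
      apply(vals, 1L, stats::quantile, 0.025)
    tab[[paste0(col, "_hi")]] <-
      apply(vals, 1L, stats::quantile, 0.975)
  }

  sp_ids <- sort(unique(covs$subperiod))
  traj_f0 <- vapply(sp_ids, function(k) {
    sel <- covs$subperiod == k
    100 * sum(an_f0[sel]) / sum(deaths[sel])
  }, 0)
  traj_cf0 <- vapply(sp_ids, function(k) {
    sel <- covs$subperiod == k
    100 * sum(an_cf0[sel]) / sum(deaths[sel])
  }, 0)
  tf <- vapply(traj_samp, function(m) m[1L, ], numeric(length(sp_ids)))
  tc <- vapply(traj_samp, function(m) m[2L, ], numeric(length(sp_ids)))
  tf <- matrix(tf, nrow = length(sp_ids))
  tc <- matrix(tc, nrow = length(sp_ids))
  trajectories <- data.frame(
    subperiod = sp_ids,
    haf_factual = traj_f0,
    haf_factual_lo = apply(tf, 1L, stats::quantile, 0.025),
    haf_factual_hi = apply(tf, 1L, stats::quantile, 0.975),
    haf_counterfactual = traj_cf0,
    haf_counterfactual_lo = apply(tc, 1L, stats::quantile, 0.025),
    haf_counterfactual_hi = apply(tc, 1L, stats::quantile, 0.975))

  units_df <- data.frame(covs[, c("city", "country", "region",
                                  "subperiod", "start_year", "hpp")],
                         an_factual = an_f0,
                         an_counterfactual = an_cf0,
                         deaths_total = deaths,
                         stringsAsFactors = FALSE)
  structure(list(table = tab, units = units_df,
                 trajectories = trajectories,
                 deaths_avoided = tab[tab$scope_type == "overall",
                                      c("deaths_avoided",
                                        "deaths_avoided_lo",
                                        "deaths_avoided_hi")],
                 n_samples = n_samples, samples = samp),
            class = "attribution_result")
}

# closure drawing one set of city random effects per call from their
# conditional distribution b | data ~ N(bhat, Psi - Psi Z' V^-1 Z Psi),
# returning the per-unit random-effect contribution matrix
raneff_sampler <- function(model, dataset) {
  parts <- meta_parts(dataset, model$formula)
  bhat <- blup_raneff(model, parts)
  p <- model$p
  facs <- lapply(parts$parts, function(pc) {
    D <- diag(model$psi, 2 * p)
    V <- pc$S + pc$Z %*% (model$psi * t(pc$Z))
    C <- D - D %*% t(pc$Z) %*% solve(V, pc$Z %*% D)
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2 * p)
  })
  n <- nrow(dataset$covs)
  tvals <- dataset$covs$time
  function() {
    rp <- matrix(0, n, p)
    for (ic in seq_along(parts$parts)) {
      pc <- parts$parts[[ic]]
      b <- bhat[[ic]] + drop(facs[[ic]] %*% stats::rnorm(2 * p))
      for (u in pc$idx)
        rp[u, ] <- b[1:p] + tvals[u] * b[(p + 1):(2 * p)]
    }
    rp
  }
}

#' Pooled relative risk at the 99th percentile under both scenarios
#'
#' Fixed-effect prediction of the pooled curve per region at a chosen
#' subperiod midpoint, with and without the HPP indicator, summarised
#' as the relative risk at the 99th percentile versus the curve's own
#' MMT.
#'
#' @param model a `"meta_model"` (needs `region`, `time`, `hpp`
#'   covariates).
#' @param dataset the fitted `"meta_dataset"`.
#' @param mid_time subperiod midpoint year (default: latest fitted).
#' @return data.frame per region with `rr99_factual`,
#'   `rr99_counterfactual`.
#' @export
scenario_rr99 <- function(model, dataset,
                          mid_time = max(dataset$covs$mid_time)) {
  tv <- mid_time - dataset$time_center
  regions <- levels(dataset$covs$region)
  vs <- dataset$var_spec
  out <- NULL
  for (rg in regions) {
    rr <- vapply(c(1, 0), function(h) {
      nd <- data.frame(region = factor(rg, levels = regions),
                       time = tv, hpp = h,
                       hppclass = factor(2, levels = 1:3))
      pf <- predict_fixed(model, nd)
      cv <- reduced_curve(pf$coef, pf$vcov, vs)
      mmt <- find_mmt(cv, range = dataset$config$mmt_range,
                      step = dataset$config$mmt_step)
      predict(center_curve(cv, mmt$mmt), 99)$rr
    }, 0)
    out <- rbind(out, data.frame(region = rg, mid_time = mid_time,
                                 rr99_factual = rr[1L],
                                 rr99_counterfactual = rr[2L]))
  }
  out
}
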