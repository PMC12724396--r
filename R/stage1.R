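#' Run configuration for the three-stage analysis
#'
#' All defaults follow the standard warm-season two-stage design:
#' three-year subperiods anchored at 1990, May-September analysis
#' window, exposure spline knots at the 50th/90th percentile, 10 days of
#' lag with two log-spaced lag knots, minimum-mortality temperature
#' (MMT) searched on the 1st-99th percentile, attribution above the 95th
#' percentile, meta-regression Model 3, and 1000 Monte-Carlo samples.
#'
#' @param block_years subperiod length in years.
#' @param anchor first year of the subperiod grid.
#' @param season analysis months.
#' @param knot_pcts internal knot percentiles of the exposure spline.
#' @param max_lag maximum lag (days).
#' @param lag_knots number of log-spaced internal lag knots.
#' @param mmt_range percentile search range for the MMT.
#' @param mmt_step grid step of the MMT search (percentile units).
#' @param threshold_pct attribution threshold percentile.
#' @param model meta-regression model id (`"model3"`, `"model4"`,
#'   `"model5"`) or a one-sided formula on the unit covariates.
#' @param n_samples Monte-Carlo samples for empirical CIs.
#' @param seed master seed.
#' @param exclude_2003 sensitivity switch: drop June-August 2003 days
#'   from the first-stage outcome and from attribution.
#' @param indicator_rule reading of the subperiod HPP indicator; see
#'   [hpp_indicator()].
#' @param min_days minimum analyzed days for a city-subperiod fit.
#' @param allow_partial include subperiods only partially covered by a
#'   city's series?
#' @param share_mmt counterfactual curve reuses the factual MMT instead
#'   of its own.
#' @param floor_af floor negative daily attributable fractions at 0.
#' @param sample_random_effects Monte-Carlo sampling perturbs random
#'   effects as well as fixed effects (default: fixed effects only).
#' @param region_mean_weighting `"pooled"` aggregates regions by pooling
#'   attributable numbers and deaths; `"unweighted"` averages country
#'   values.
#'
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(block_years = 3L, anchor = 1990L,
                       season = 5:9, knot_pcts = c(50, 90),
                       max_lag = 10L, lag_knots = 2L,
                       mmt_range = c(1, 99), mmt_step = 0.1,
                       threshold_pct = 95, model = "model3",
                       n_samples = 1000L, seed = 1L,
                       exclude_2003 = FALSE,
                       indicator_rule = "full_coverage",
                       min_days = 270L, allow_partial = TRUE,
                       share_mmt = FALSE, floor_af = TRUE,
                       sample_random_effects = FALSE,
                       region_mean_weighting = c("pooled",
                                                 "unweighted")) {
  structure(list(block_years = as.integer(block_years),
                 anchor = as.integer(anchor), season = season,
                 knot_pcts = knot_pcts, max_lag = as.integer(max_lag),
                 lag_knots = as.integer(lag_knots),
                 mmt_range = mmt_range, mmt_step = mmt_step,
                 threshold_pct = threshold_pct, model = model,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed), exclude_2003 = exclude_2003,
                 indicator_rule = indicator_rule,
                 min_days = as.integer(min_days),
                 allow_partial = allow_partial, share_mmt = share_mmt,
                 floor_af = floor_af,
                 sample_random_effects = sample_random_effects,
                 region_mean_weighting =
                   match.arg(region_mean_weighting)),
            class = "run_config")
}

#' Split a location series into aligned analysis subperiods
#'
#' Subperiods are consecutive `block_years`-year blocks aligned to the
#' anchor year (1990 + 3k by default) regardless of when the city's
#' series starts.  Outcome rows are the warm-season days of the block
#' with a complete lag window; the lag window itself is allowed to reach
#' back into the preceding calendar days (late April), so only the first
#' `max_lag` days of the whole series are excluded.
#'
#' @param series data.frame with at least `date`.
#' @param config a [run_config()].
#'
#' @return List of subperiods, each a list with `index`, `start_year`,
#'   `end_year`, `mid_time`, `outcome_rows` (row indices into `series`),
#'   `n_years` (city years covered).  Blocks with fewer than
#'   `config$min_days` outcome days are dropped; with
#'   `allow_partial = FALSE`, blocks not fully covered by the series are
#'   dropped too.
#' @export
split_subperiods <- function(series, config = run_config()) {
  dp <- date_parts(series$date)
  incomplete <- seq_len(nrow(series)) <= config$max_lag
  seas <- dp$month %in% config$season
  drop2003 <- if (isTRUE(config$exclude_2003))
    dp$year == 2003L & dp$month %in% 6:8 else rep(FALSE, nrow(series))
  yr <- range(dp$year)
  k0 <- floor((yr[1L] - config$anchor) / config$block_years)
  k1 <- floor((yr[2L] - config$anchor) / config$block_years)
  out <- list()
  for (k in k0:k1) {
    sy <- config$anchor + k * config$block_years
    ey <- sy + config$block_years - 1L
    if (!config$allow_partial && (sy < yr[1L] || ey > yr[2L])) next
    rows <- which(dp$year >= sy & dp$year <= ey & seas & !incomplete &
                    !drop2003)
    if (length(rows) < config$min_days) next
    out[[length(out) + 1L]] <- list(
      index = k + 1L, start_year = sy, end_year = ey,
      mid_time = sy + (config$block_years - 1) / 2,
      outcome_rows = rows,
      n_years = length(unique(dp$year[rows])))
  }
  out
}

#' First-stage design matrix
#'
#' Columns: intercept; a natural cubic spline with 4 df for day of the
#' season (days since 30 April) interacted with a per-calendar-year
#' indicator (a separate seasonal curve per year); 6 day-of-week
#' dummies (Sunday as reference); and the 16 cross-basis columns.
#'
#' @param dates outcome-day dates.
#' @param cb cross-basis rows for the same days.
#'
#' @return List with `x` (design matrix), `cb_cols` (column indices of
#'   the cross-basis block) and `aliased_ok` (FALSE when rank
#'   deficiency involves the cross-basis and the fit must be flagged).
#' @export
build_design <- function(dates, cb) {
  dp <- date_parts(dates)
  dos <- dp$doy - (date_parts(as.Date(sprintf("%d-04-30",
                                              dp$year)))$doy)
  seas_b <- splines::ns(dos, df = 4)
  yrs <- sort(unique(dp$year))
  seas <- NULL
  for (y in yrs) seas <- cbind(seas, seas_b * (dp$year == y))
  colnames(seas) <- paste0("seas", rep(yrs, each = 4L), "_",
                           rep(1:4, length(yrs)))
  doww <- factor(dp$wday, levels = 1:7)
  dow <- stats::model.matrix(~doww)[, -1L, drop = FALSE]
  x <- cbind(`(Intercept)` = 1, seas, dow, cb)
  cb_cols <- (ncol(x) - ncol(cb) + 1L):ncol(x)
  qrx <- qr(x)
  aliased_ok <- TRUE
  if (qrx$rank < ncol(x)) {
    dropped <- qrx$pivot[-seq_len(qrx$rank)]
    if (any(dropped %in% cb_cols)) {
      aliased_ok <- FALSE
    } else {
      keep <- sort(qrx$pivot[seq_len(qrx$rank)])
      x <- x[, keep, drop = FALSE]
      cb_cols <- which(keep %in% cb_cols)
    }
  }
  list(x = x, cb_cols = cb_cols, aliased_ok = aliased_ok)
}

#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Point estimates are the Poisson maximum-likelihood estimates (log
#' link); the quasi-Poisson dispersion is estimated as the Pearson
#' statistic over `n - p`, and the covariance is the Poisson information
#' inverse scaled by the dispersion.
#'
#' @param y nonnegative integer counts.
#' @param x full-rank design matrix.
#'
#' @return List with `coef`, `vcov`, `vcov_unscaled`, `dispersion`,
#'   `fitted`, `converged`, `n`, `p`.
#' @export
fit_quasipoisson <- function(y, x) {
  if (any(y < 0) || any(y != round(y))) stop("'y' must be counts")
  if (sum(y) == 0) stop("all-zero outcome; block rejected")
  fit <- stats::glm.fit(x, y, family = stats::poisson(),
                        control = list(epsilon = 1e-8, maxit = 100L))
  mu <- fit$fitted.values
  n <- length(y); p <- ncol(x)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  xtwx <- crossprod(x * sqrt(mu))
  vun <- chol2inv(chol(xtwx))
  list(coef = fit$coefficients, vcov = phi * vun, vcov_unscaled = vun,
       dispersion = phi, fitted = mu, converged = fit$converged,
       n = n, p = p)
}

#' Fit all location-subperiod quasi-Poisson DLNMs
#'
#' For each city: the full-period warm-season percentile table is
#' computed, daily temperatures are mapped to the percentile scale, the
#' cross-basis is built over the whole daily series (so lag windows may
#' reach back before 1 May), and one model is fitted per subperiod.
#' Each fitted cross-basis is reduced to the overall cumulative curve,
#' the MMT located, and the curve centered there.
#'
#' @param cohort an `"hpp_cohort"` (or any list with `series` and
#'   `meta` in the same shape).
#' @param config a [run_config()].
#'
#' @return Object of class `"stage1_fits"`: list with `fits` (one
#'   record per converged city-subperiod: city/region/country ids,
#'   subperiod, reduced `coef` and `vcov`, `mmt_pct`, `mmt_c`,
#'   `dispersion`, `n_days`, `n_years`), `city_tables` (percentile
#'   tables), `var_spec`, `lag_spec`, `config`, and `failures` (count of
#'   rejected blocks).
#' @export
first_stage <- function(cohort, config = run_config()) {
  var_spec <- var_basis_spec(knots = config$knot_pcts,
                             boundary = c(0, 100))
  lag_spec <- lag_basis_spec(config$max_lag, config$lag_knots)
  fits <- list()
  city_tables <- list()
  failures <- 0L
  for (city_id in names(cohort$series)) {
    ser <- cohort$series[[city_id]]
    m <- cohort$meta[match(city_id, cohort$meta$city_id), ]
    tab <- pct_table(ser$tmean, ser$date, config$season)
    city_tables[[city_id]] <- tab
    pct <- to_percentile(ser$tmean, tab)
    cb <- cross_basis(pct, var_spec, lag_spec)
    for (s in split_subperiods(ser, config)) {
      rows <- s$outcome_rows
      des <- build_design(ser$date[rows], cb[rows, , drop = FALSE])
      if (!des$aliased_ok) { failures <- failures + 1L; next }
      fit <- tryCatch(fit_quasipoisson(ser$deaths[rows], des$x),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { failures <- failures + 1L; next }
      curve <- reduce_to_overall(fit$coef[des$cb_cols],
                                 fit$vcov[des$cb_cols, des$cb_cols],
                                 var_spec, lag_spec)
      mmt <- find_mmt(curve, range = config$mmt_range,
                      step = config$mmt_step)
      curve <- center_curve(curve, mmt$mmt)
      fits[[length(fits) + 1L]] <- list(
        city_id = city_id, country = m$country, region = m$region,
        population = m$population, subperiod = s$index,
        start_year = s$start_year, end_year = s$end_year,
        mid_time = s$mid_time, coef = curve$coef, vcov = curve$vcov,
        mmt_pct = mmt$mmt, mmt_c = from_percentile(mmt$mmt, tab),
        dispersion = fit$dispersion, n_days = fit$n,
        n_years = s$n_years, converged = TRUE)
    }
  }
  structure(list(fits = fits, city_tables = city_tables,
                 var_spec = var_spec, lag_spec = lag_spec,
                 config = config, failures = failures),
            class = "stage1_fits")
}
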