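#' Ground-truth parameters for the synthetic multi-city generator
#'
#' Encodes the data-generating assumptions of the analysis: overdispersed
#' daily death counts with a lagged, non-linear heat effect above a
#' minimum-mortality temperature (MMT), seasonal and weekly cycles,
#' region-specific temporal trends in heat risk, and a heat prevention
#' plan (HPP) that multiplies the above-MMT log-risk slope by
#' `hpp_effect` from 1 January of each country's implementation year.
#' The true exposure-response is piecewise linear on the percentile
#' scale: zero at or below the MMT percentile, rising linearly so that
#' the log relative risk at the 99th percentile equals the (time- and
#' HPP-adjusted) regional slope.
#'
#' Default values emulate a European-style study: 102 cities in 14
#' countries across four regions observed 1990-2019, ~20 expected deaths
#' per city-day, decreasing heat risk in the Southern/Western regions
#' and increasing risk in the Northern/Eastern regions, and staggered
#' national HPP implementation years in 2003-2013.
#'
#' @param n_cities number of cities.
#' @param countries data.frame with columns `country`, `region` (one of
#'   Northern/Eastern/Western/Southern), `hpp_year` (integer or NA),
#'   and optionally `start_year` (unequal series timespans).
#' @param years inclusive year range of the daily series.
#' @param baseline_rate expected daily deaths per city (> 0).
#' @param overdispersion variance inflation factor psi >= 1 (counts are
#'   gamma-Poisson with variance `psi * mean`).
#' @param mmt_pct percentile of the true MMT (0-100).
#' @param heat_slope named vector (per region) of the true log-RR at the
#'   99th temperature percentile in `ref_year`, counterfactual scale.
#' @param slope_trend named vector (per region): change of that log-RR
#'   per decade.
#' @param ref_year calendar year at which `heat_slope` applies.
#' @param lag_weights nonnegative weights over lags 0..10 summing to 1.
#' @param hpp_effect multiplicative factor in (0, 1] applied to the
#'   above-MMT slope from implementation onward; 1 = no effect.
#' @param season_amp seasonal amplitude of baseline mortality (cosine
#'   with winter peak).
#' @param dow_effects 7 day-of-week multipliers (Sunday first).
#' @param climate data.frame of per-region temperature parameters
#'   (`region`, `mean`, `amplitude`, `noise_sd`, `ar`, `hw_rate`,
#'   `hw_len`, `hw_amp`).
#' @param seed integer master seed.
#'
#' @return Object of class `"truth_params"`.
#' @export
truth_params <- function(n_cities = 102L,
                         countries = default_countries(),
                         years = c(1990L, 2019L),
                         baseline_rate = 20,
                         overdispersion = 1.3,
                         mmt_pct = 75,
                         heat_slope = c(Northern = 0.18, Eastern = 0.30,
                                        Western = 0.38, Southern = 0.55),
                         slope_trend = c(Northern = 0.07, Eastern = 0.05,
                                         Western = -0.06,
                                         Southern = -0.12),
                         ref_year = 2005,
                         lag_weights = default_lag_weights(),
                         hpp_effect = 0.7,
                         season_amp = 0.15,
                         dow_effects = c(1.02, 1.00, 0.99, 0.99, 1.00,
                                         1.00, 1.01),
                         climate = default_climate(),
                         seed = 42L) {
  lag_weights <- as.numeric(lag_weights)
  if (any(lag_weights < 0) || abs(sum(lag_weights) - 1) > 1e-12)
    stop("'lag_weights' must be nonnegative and sum to 1")
  if (overdispersion < 1) stop("'overdispersion' must be >= 1")
  if (hpp_effect <= 0 || hpp_effect > 1)
    stop("'hpp_effect' must be in (0, 1]")
  if (mmt_pct <= 0 || mmt_pct >= 100) stop("'mmt_pct' must be in (0, 100)")
  if (baseline_rate <= 0) stop("'baseline_rate' must be > 0")
  if (length(years) != 2L || years[1L] > years[2L])
    stop("'years' must be an inclusive year range")
  regs <- unique(countries$region)
  if (!all(regs %in% names(heat_slope)) ||
      !all(regs %in% names(slope_trend)))
    stop("'heat_slope'/'slope_trend' must name every region")
  if (!all(regs %in% climate$region))
    stop("'climate' must cover every region")
  if (length(dow_effects) != 7L) stop("'dow_effects' must have length 7")
  if (is.null(countries$start_year)) countries$start_year <- years[1L]
  structure(list(n_cities = as.integer(n_cities), countries = countries,
                 years = as.integer(years), baseline_rate = baseline_rate,
                 overdispersion = overdispersion, mmt_pct = mmt_pct,
                 heat_slope = heat_slope, slope_trend = slope_trend,
                 ref_year = ref_year, lag_weights = lag_weights,
                 max_lag = length(lag_weights) - 1L,
                 hpp_effect = hpp_effect, season_amp = season_amp,
                 dow_effects = as.numeric(dow_effects),
                 climate = climate, seed = as.integer(seed)),
            class = "truth_params")
}

#' @rdname truth_params
#' @export
default_countries <- function() {
  data.frame(
    country = c("N1", "N2", "N3",
                "E1", "E2", "E3", "E4",
                "W1", "W2", "W3", "W4",
                "S1", "S2", "S3"),
    region = c(rep("Northern", 3L), rep("Eastern", 4L),
               rep("Western", 4L), rep("Southern", 3L)),
    hpp_year = c(2011L, 2013L, 2004L,
                 2006L, 2012L, 2008L, 2010L,
                 2004L, 2005L, 2007L, 2005L,
                 2004L, 2004L, 2006L),
    stringsAsFactors = FALSE)
}

#' @rdname truth_params
#' @export
default_lag_weights <- function(max_lag = 10L, decay = 0.7) {
  w <- exp(-decay * (0:max_lag))
  w / sum(w)
}

#' @rdname truth_params
#' @export
default_climate <- function() {
  data.frame(
    region = c("Northern", "Eastern", "Western", "Southern"),
    mean = c(6, 10, 11, 16),
    amplitude = c(9, 10, 7, 8),
    noise_sd = c(3, 3, 3, 2.5),
    ar = c(0.7, 0.7, 0.7, 0.7),
    hw_rate = c(1, 1.5, 1.5, 2),
    hw_len = c(4, 4, 4, 5),
    hw_amp = c(4, 5, 4, 4),
    stringsAsFactors = FALSE)
}

#' Simulate a daily mean temperature series
#'
#' Stationary seasonal cycle (cosine peaking mid-July) plus AR(1) noise
#' plus superimposed multi-day heatwave excursions (half-sine bumps) in
#' the warm season.
#'
#' @param years inclusive year range `c(first, last)`.
#' @param mean annual mean temperature (degrees C).
#' @param amplitude seasonal half-range.
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param ar lag-1 autocorrelation in `[0, 1)`.
#' @param hw_rate expected heatwave episodes per warm season (>= 0).
#' @param hw_len mean episode duration in days.
#' @param hw_amp peak episode amplitude (degrees C).
#' @param seed optional integer seed.
#'
#' @return data.frame with `date` and `tmean`; heatwave episodes are
#'   recorded in the `"heatwaves"` attribute.
#' @export
simulate_temperature <- function(years, mean = 12, amplitude = 8,
                                 noise_sd = 3, ar = 0.7, hw_rate = 1.5,
                                 hw_len = 4, hw_amp = 4, seed = NULL) {
  if (length(years) != 2L || anyNA(years) || years[1L] > years[2L])
    stop("invalid 'years' range")
  for (nm in c("mean", "amplitude", "noise_sd", "ar", "hw_rate",
               "hw_len", "hw_amp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite number")
  }
  if (ar < 0 || ar >= 1) stop("parameter 'ar' must be in [0, 1)")
  if (hw_rate < 0) stop("parameter 'hw_rate' must be >= 0")
  if (noise_sd < 0) stop("parameter 'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  dates <- seq(as.Date(sprintf("%d-01-01", years[1L])),
               as.Date(sprintf("%d-12-31", years[2L])), by = "day")
  n <- length(dates)
  dp <- date_parts(dates)
  seasonal <- mean + amplitude * cos(2 * pi * (dp$doy - 196) / 365.25)

  noise <- numeric(n)
  if (noise_sd > 0) {
    innov <- stats::rnorm(n, 0, noise_sd * sqrt(1 - ar^2))
    noise <- as.numeric(stats::filter(innov, ar, method = "recursive"))
  }

  tmean <- seasonal + noise
  hw <- NULL
  if (hw_rate > 0) {
    yrs <- years[1L]:years[2L]
    for (y in yrs) {
      idx <- which(dp$year == y & dp$month %in% SEASON_MONTHS)
      n_ep <- stats::rpois(1L, hw_rate)
      if (n_ep == 0L) next
      for (e in seq_len(n_ep)) {
        dur <- 2L + stats::rpois(1L, max(hw_len - 2, 0))
        s <- idx[1L] + sample.int(max(length(idx) - dur, 1L), 1L) - 1L
        days <- s:min(s + dur - 1L, n)
        bump <- hw_amp * sin(pi * seq_along(days) / (length(days) + 1))
        tmean[days] <- tmean[days] + bump
        hw <- rbind(hw, data.frame(year = y, start = dates[s],
                                   duration = length(days)))
      }
    }
  }
  structure(data.frame(date = dates, tmean = tmean),
            heatwaves = hw)
}

# true overall-cumulative log relative risk on the percentile scale:
# zero at/below the MMT percentile, linear up to log(RR99) at p = 99
true_log_rr <- function(pct, slope, mmt_pct) {
  slope * pmax(0, (pct - mmt_pct) / (99 - mmt_pct))
}

# region slope at a given (fractional) year, floored at 0
slope_at <- function(truth, region, year) {
  pmax(0, truth$heat_slope[[region]] +
         truth$slope_trend[[region]] * (year - truth$ref_year) / 10)
}

#' Simulate daily death counts for one location
#'
#' Expected deaths combine a seasonal baseline (winter-peaking cosine),
#' day-of-week multipliers and the lagged heat effect
#' \eqn{\exp(s_t \sum_l w_l u(p_{t-l}))}, where `u` is the true
#' piecewise-linear exposure-response on the percentile scale, `w` the
#' lag weights, and `s_t` the region slope at day t scaled by the HPP
#' factor (`hpp_effect` from 1 January of the implementation year).
#' Counts are Poisson when `overdispersion == 1` and gamma-Poisson
#' (negative binomial, variance `psi * mean`) otherwise.
#'
#' @param temp data.frame with `date`, `tmean` (from
#'   [simulate_temperature()]).
#' @param truth a [truth_params()] object.
#' @param region,country city context; `country` selects the HPP year.
#' @param hpp_year implementation year (NA = never); defaults to the
#'   country's entry in `truth$countries`.
#' @param seed optional integer seed.
#'
#' @return data.frame `date`, `tmean`, `deaths` with attributes
#'   `pct_table` and `expected` (the true mean series); the first
#'   `max_lag` days are burn-in (attribute `burnin`).
#' @export
simulate_mortality <- function(temp, truth, region, country = NULL,
                               hpp_year = NULL, seed = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  if (truth$overdispersion < 1) stop("'overdispersion' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(hpp_year)) {
    if (is.null(country)) stop("give 'country' or 'hpp_year'")
    i <- match(country, truth$countries$country)
    if (is.na(i)) stop("unknown country: ", country)
    hpp_year <- truth$countries$hpp_year[i]
  }
  dates <- temp$date
  if (length(dates) <= truth$max_lag)
    stop("series must cover more than 'max_lag' days")
  dp <- date_parts(dates)
  tab <- pct_table(temp$tmean, dates)
  pct <- to_percentile(temp$tmean, tab)

  u <- pmax(0, (pct - truth$mmt_pct) / (99 - truth$mmt_pct))
  lagu <- as.numeric(stats::filter(u, truth$lag_weights,
                                   method = "convolution", sides = 1))
  lagu[seq_len(truth$max_lag)] <- 0 # burn-in days

  yearfrac <- dp$year + (dp$doy - 1) / 365.25
  slope <- slope_at(truth, region, yearfrac)
  hppfac <- if (is.na(hpp_year)) 1
            else ifelse(dp$year >= hpp_year, truth$hpp_effect, 1)
  season <- 1 + truth$season_amp * cos(2 * pi * (dp$doy - 1) / 365.25)
  dow <- truth$dow_effects[dp$wday]
  mu <- truth$baseline_rate * season * dow * exp(slope * hppfac * lagu)

  psi <- truth$overdispersion
  deaths <- if (psi == 1) stats::rpois(length(mu), mu)
            else stats::rnbinom(length(mu), mu = mu,
                                size = mu / (psi - 1))
  structure(data.frame(date = dates, tmean = temp$tmean,
                       deaths = as.integer(deaths)),
            pct_table = tab, expected = mu,
            burnin = seq_along(dates) <= truth$max_lag)
}
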