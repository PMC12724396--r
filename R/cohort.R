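#' Generate a synthetic multi-city cohort with known ground truth
#'
#' Builds one daily temperature/mortality series per city (cities spread
#' as evenly as possible over the countries of `truth$countries`, each
#' country belonging to one of four regions), a heat prevention plan
#' catalogue with per-country scores and tercile classes, and the truth
#' record needed for parameter-recovery experiments.  Fully
#' deterministic under `truth$seed`.
#'
#' @param truth a [truth_params()] object.
#'
#' @return Object of class `"hpp_cohort"`: list with `series` (named
#'   list of data.frames `date`, `tmean`, `deaths`), `meta`
#'   (city-level metadata including region, country and 2015-style
#'   population), `catalogue` (country, hpp_year, element scores, total
#'   score, class) and `truth`.
#' @export
build_cohort <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  set.seed(truth$seed)
  ctry <- truth$countries
  nc <- nrow(ctry)
  assign <- sort(rep_len(seq_len(nc), truth$n_cities))

  series <- list()
  meta <- NULL
  for (i in seq_len(truth$n_cities)) {
    row <- ctry[assign[i], ]
    cl <- truth$climate[match(row$region, truth$climate$region), ]
    city_id <- sprintf("%s_c%02d", row$country,
                       sum(assign[seq_len(i)] == assign[i]))
    mean_i <- cl$mean + stats::rnorm(1L, 0, 1.5)
    amp_i <- cl$amplitude * stats::runif(1L, 0.9, 1.1)
    pop_i <- round(stats::rlnorm(1L, log(4e5), 0.6))
    yrs <- c(max(row$start_year, truth$years[1L]), truth$years[2L])
    temp <- simulate_temperature(yrs, mean = mean_i, amplitude = amp_i,
                                 noise_sd = cl$noise_sd, ar = cl$ar,
                                 hw_rate = cl$hw_rate, hw_len = cl$hw_len,
                                 hw_amp = cl$hw_amp)
    ser <- simulate_mortality(temp, truth, region = row$region,
                              hpp_year = row$hpp_year)
    series[[city_id]] <- ser
    meta <- rbind(meta, data.frame(
      city_id = city_id, country = row$country, region = row$region,
      population = pop_i, series_start = min(ser$date),
      series_end = max(ser$date), stringsAsFactors = FALSE))
  }

  catalogue <- simulate_catalogue(ctry)
  structure(list(series = series, meta = meta, catalogue = catalogue,
                 truth = truth),
            class = "hpp_cohort")
}

# synthetic HPP catalogue: 8 core elements x 3 candidate actions, expert
# weights in {0, 0.5, ..., 2}; Southern/Western countries tend to have
# more developed plans than Northern/Eastern ones
simulate_catalogue <- function(countries, n_actions = 3L) {
  n_el <- 8L
  max_score <- n_el * n_actions * 2
  out <- NULL
  for (i in seq_len(nrow(countries))) {
    f <- if (countries$region[i] %in% c("Southern", "Western"))
      stats::runif(1L, 0.55, 0.9) else stats::runif(1L, 0.2, 0.6)
    w <- 0.5 * stats::rbinom(n_el * n_actions, 4L, f)
    el <- colSums(matrix(w, nrow = n_actions))
    rec <- data.frame(country = countries$country[i],
                      hpp_year = countries$hpp_year[i],
                      stringsAsFactors = FALSE)
    for (e in seq_len(n_el)) rec[[paste0("element_", e)]] <- el[e]
    rec$total_score <- sum(w)
    out <- rbind(out, rec)
  }
  out$hpp_class <- classify_hpp(out$total_score, max_score)
  attr(out, "max_score") <- max_score
  validate_catalogue(out)
}

#' Ground-truth heat attribution for a synthetic cohort
#'
#' Evaluates the known true exposure-response (not the fitted one) on
#' every post-implementation warm-season day hotter than the chosen
#' percentile threshold, exactly mirroring the estimator's attribution
#' arithmetic: daily attributable fraction `(RR - 1)/RR`, attributable
#' numbers `deaths * AF`, heat-attributable fraction (HAF, % of all
#' warm-season deaths) and annual attributable death rate per 100 000
#' (HAD).  The factual scenario uses the HPP factor as generated
#' (day-level switch at 1 January of the implementation year); the
#' counterfactual forces the factor to 1.
#'
#' @param truth the [truth_params()] the cohort was generated from.
#' @param cohort the matching [build_cohort()] output.
#' @param config a [run_config()]; the subperiod split, season window,
#'   threshold percentile and indicator rule are taken from it.
#'
#' @return List with overall `haf_factual`, `haf_counterfactual`,
#'   `haf_change` (%), `had_factual`, `had_counterfactual`,
#'   `had_difference` (annual per 100 000), `deaths_avoided`, and a
#'   per-unit data.frame `units`.
#' @export
true_attribution <- function(truth, cohort, config = run_config()) {
  stopifnot(inherits(cohort, "hpp_cohort"))
  if (!identical(truth, cohort$truth))
    stop("'truth' does not match the cohort's truth record")
  thr <- config$threshold_pct
  an_f <- an_cf <- deaths_tot <- 0
  person_years <- 0
  units <- NULL
  for (city_id in names(cohort$series)) {
    ser <- cohort$series[[city_id]]
    m <- cohort$meta[match(city_id, cohort$meta$city_id), ]
    hpp_year <- truth$countries$hpp_year[
      match(m$country, truth$countries$country)]
    tab <- pct_table(ser$tmean, ser$date, config$season)
    pct <- to_percentile(ser$tmean, tab)
    dp <- date_parts(ser$date)
    yearfrac <- dp$year + (dp$doy - 1) / 365.25
    sp <- split_subperiods(ser, config)
    for (s in sp) {
      ind <- hpp_indicator(hpp_year, s$start_year, s$end_year,
                           rule = config$indicator_rule)
      if (ind == 0L) next
      rows <- s$outcome_rows
      d <- ser$deaths[rows]
      p <- pct[rows]
      slope <- slope_at(truth, m$region, yearfrac[rows])
      hppfac <- ifelse(dp$year[rows] >= hpp_year, truth$hpp_effect, 1)
      hot <- p > thr
      af_f <- 1 - exp(-true_log_rr(p[hot], slope[hot] * hppfac[hot],
                                   truth$mmt_pct))
      af_cf <- 1 - exp(-true_log_rr(p[hot], slope[hot], truth$mmt_pct))
      uf <- sum(d[hot] * pmax(af_f, 0))
      ucf <- sum(d[hot] * pmax(af_cf, 0))
      an_f <- an_f + uf; an_cf <- an_cf + ucf
      deaths_tot <- deaths_tot + sum(d)
      person_years <- person_years + m$population * s$n_years
      units <- rbind(units, data.frame(
        city_id = city_id, subperiod = s$index, an_factual = uf,
        an_counterfactual = ucf, deaths = sum(d),
        stringsAsFactors = FALSE))
    }
  }
  if (deaths_tot == 0)
    stop("no post-implementation units in cohort")
  haf_f <- 100 * an_f / deaths_tot
  haf_cf <- 100 * an_cf / deaths_tot
  list(haf_factual = haf_f, haf_counterfactual = haf_cf,
       haf_change = if (haf_cf > 0) (haf_f - haf_cf) / haf_cf * 100
                    else 0,
       had_factual = an_f / person_years * 1e5,
       had_counterfactual = an_cf / person_years * 1e5,
       had_difference = (an_f - an_cf) / person_years * 1e5,
       deaths_avoided = an_cf - an_f,
       units = units)
}

#' Write / read a cohort as plain-text files
#'
#' One CSV per city (`date`, `tmean`, `deaths`), a metadata CSV, the
#' catalogue CSV and the truth record as JSON.
#'
#' @param cohort an `"hpp_cohort"`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hpp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (city_id in names(cohort$series)) {
    ser <- cohort$series[[city_id]]
    utils::write.csv(
      data.frame(date = format(ser$date, "%Y-%m-%d"),
                 tmean = ser$tmean, deaths = ser$deaths),
      file.path(dir, paste0(city_id, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$catalogue, file.path(dir, "catalogue.csv"),
                   row.names = FALSE)
  tr <- unclass(cohort$truth)
  tr$heat_slope <- as.list(tr$heat_slope)    # keep region names in JSON
  tr$slope_trend <- as.list(tr$slope_trend)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  catalogue <- utils::read.csv(file.path(dir, "catalogue.csv"),
                               stringsAsFactors = FALSE)
  series <- list()
  for (city_id in meta$city_id) {
    ser <- utils::read.csv(file.path(dir, paste0(city_id, ".csv")),
                           stringsAsFactors = FALSE)
    ser$date <- as.Date(ser$date)
    series[[city_id]] <- ser
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tl <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- truth_params(
      n_cities = tl$n_cities, countries = tl$countries,
      years = tl$years, baseline_rate = tl$baseline_rate,
      overdispersion = tl$overdispersion, mmt_pct = tl$mmt_pct,
      heat_slope = unlist(tl$heat_slope),
      slope_trend = unlist(tl$slope_trend), ref_year = tl$ref_year,
      lag_weights = tl$lag_weights, hpp_effect = tl$hpp_effect,
      season_amp = tl$season_amp, dow_effects = tl$dow_effects,
      climate = tl$climate, seed = tl$seed)
  }
  structure(list(series = series, meta = meta, catalogue = catalogue,
                 truth = truth),
            class = "hpp_cohort")
}
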