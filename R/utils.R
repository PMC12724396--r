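# internal helpers shared across stages

# months of the warm-season analysis window (May-September)
SEASON_MONTHS <- 5:9

date_parts <- function(dates) {
  lt <- as.POSIXlt(dates)
  list(year = lt$year + 1900L, month = lt$mon + 1L, doy = lt$yday + 1L,
       wday = lt$wday + 1L)
}

in_season <- function(dates, season = SEASON_MONTHS) {
  date_parts(dates)$month %in% season
}

#' Full-period percentile table of warm-season temperatures
#'
#' Empirical quantiles (percentiles 0-100) of a location's May-September
#' daily mean temperature over the whole study period.  This table
#' defines the monotone map between absolute temperature and the
#' percentile scale on which exposure-response curves are expressed and
#' pooled.
#'
#' @param tmean daily temperature series.
#' @param dates matching dates.
#' @param season months included (default May-September).
#' @return Numeric vector of 101 temperatures named by percentile 0-100.
#' @export
pct_table <- function(tmean, dates, season = SEASON_MONTHS) {
  x <- tmean[in_season(dates, season)]
  if (!length(x)) stop("no warm-season days in series")
  stats::quantile(x, probs = 0:100 / 100, names = TRUE, type = 7)
}

# temperature -> percentile (clamped linear interpolation of the table)
to_percentile <- function(x, table) {
  q <- as.numeric(table)
  if (diff(range(q)) == 0)
    stop("percentile transform undefined for a constant temperature series")
  stats::approx(q, 0:100, xout = x, rule = 2, ties = "ordered")$y
}

# percentile -> temperature
from_percentile <- function(p, table) {
  stats::approx(0:100, as.numeric(table), xout = p, rule = 2)$y
}

# quadratic-form diagonal: rowSums((X %*% V) * X)
quad_diag <- function(x, v) rowSums((x %*% v) * x)

is_psd <- function(m, tol = 1e-10) {
  if (max(abs(m - t(m))) > 1e-8) return(FALSE)
  min(eigen((m + t(m)) / 2, symmetric = TRUE,
            only.values = TRUE)$values) >= -tol
}

# deterministic per-stage seed split from a master seed (kept < 2^31)
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + k * 7919) %% 2147483629)
}
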