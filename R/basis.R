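#' Exposure basis specification
#'
#' Defines the quadratic B-spline basis used for the exposure
#' (temperature) dimension of the cross-basis.  With two internal knots
#' and the intercept column dropped the basis has dimension 4.  In the
#' standard configuration the basis lives on the percentile scale of the
#' location's full-period warm-season temperature distribution, with
#' internal knots at the 50th and 90th percentile and boundary knots at
#' 0 and 100.
#'
#' @param knots numeric vector of strictly increasing internal knots.
#' @param boundary length-2 numeric vector enclosing the internal knots.
#' @param degree spline degree; quadratic (2) by default.
#'
#' @return An object of class `"var_basis_spec"`.
#' @export
var_basis_spec <- function(knots = c(50, 90), boundary = c(0, 100),
                           degree = 2L) {
  knots <- as.numeric(knots)
  boundary <- as.numeric(boundary)
  if (anyNA(knots) || is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be finite and strictly increasing")
  if (length(boundary) != 2L || anyNA(boundary) ||
      boundary[1L] >= boundary[2L])
    stop("'boundary' must be two increasing finite values")
  if (min(knots) <= boundary[1L] || max(knots) >= boundary[2L])
    stop("'boundary' must strictly enclose the internal 'knots'")
  structure(list(knots = knots, boundary = boundary,
                 degree = as.integer(degree),
                 dim = length(knots) + as.integer(degree)),
            class = "var_basis_spec")
}

#' Lag basis specification
#'
#' Natural cubic spline over the lag dimension, with an intercept column
#' (the lag-constant component needed for the overall cumulative effect)
#' and internal knots equally spaced on the log-lag scale.
#'
#' @param max_lag maximum lag in days (default 10).
#' @param n_knots number of internal knots (default 2), placed by
#'   [log_lag_knots()].
#'
#' @return An object of class `"lag_basis_spec"` with elements
#'   `max_lag`, `knots` and `dim` (`n_knots + 2`).
#' @export
lag_basis_spec <- function(max_lag = 10L, n_knots = 2L) {
  kn <- log_lag_knots(max_lag, n_knots)
  structure(list(max_lag = as.integer(max_lag), knots = kn,
                 boundary = c(0, max_lag),
                 dim = length(kn) + 2L),
            class = "lag_basis_spec")
}

#' Knots equally spaced on the log-lag scale
#'
#' Lag 0 cannot be log-transformed, so the knots divide
#' `[log(1), log(max_lag)]` into `n_knots + 1` equal parts and the knots
#' sit at the interior division points.  With `max_lag = 10` and two
#' knots this gives `10^(1/3)` and `10^(2/3)`.
#'
#' @param max_lag maximum lag (>= 1).
#' @param n_knots number of internal knots; must be < `max_lag`.
#'
#' @return Numeric vector of knot positions in `(0, max_lag)`.
#' @export
log_lag_knots <- function(max_lag, n_knots = 2L) {
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 1)
    stop("'max_lag' must be a single value >= 1")
  if (n_knots < 1L) stop("'n_knots' must be >= 1")
  if (n_knots >= max_lag) stop("'n_knots' must be smaller than 'max_lag'")
  exp(seq(log(1), log(max_lag), length.out = n_knots + 2L))[2L:(n_knots + 1L)]
}

#' Quadratic B-spline basis with clamped extrapolation
#'
#' Evaluates the B-spline family defined by `spec` through the
#' Cox-de Boor recursion ([splines::splineDesign()]).  The first column
#' of the full family is dropped unless `intercept = TRUE`, so the
#' default dimension with two internal knots is 4.  Values outside the
#' boundary knots are evaluated by constant extrapolation of the
#' boundary basis values (clamping), which prevents wild quadratic
#' extrapolation at record temperatures.
#'
#' @param x numeric vector of exposure values.
#' @param spec a [var_basis_spec()].
#' @param intercept keep the full family (which sums to 1)?
#'
#' @return Numeric matrix with `length(x)` rows.
#' @export
bspline_basis <- function(x, spec = var_basis_spec(), intercept = FALSE) {
  stopifnot(inherits(spec, "var_basis_spec"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  deg <- spec$degree
  xc <- pmin(pmax(x, spec$boundary[1L]), spec$boundary[2L])
  akn <- c(rep(spec$boundary[1L], deg + 1L), spec$knots,
           rep(spec$boundary[2L], deg + 1L))
  b <- splines::splineDesign(akn, xc, ord = deg + 1L)
  if (!intercept) b <- b[, -1L, drop = FALSE]
  b
}

#' Natural cubic spline basis
#'
#' Natural cubic spline family (second derivative zero at the boundary
#' knots, linear beyond them) with an optional intercept column.  Used
#' for the lag dimension of the cross-basis and for the seasonal control
#' spline in the first-stage regression.
#'
#' @param x numeric vector.
#' @param knots internal knots, strictly increasing and inside
#'   `boundary`.
#' @param boundary length-2 boundary knots.
#' @param intercept prepend a constant column (default `TRUE`, giving
#'   dimension `length(knots) + 2`).
#'
#' @return Numeric matrix with `length(x)` rows.
#' @export
natural_cubic_basis <- function(x, knots, boundary = range(x),
                                intercept = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be finite numeric")
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be strictly increasing")
  if (min(knots) <= boundary[1L] || max(knots) >= boundary[2L])
    stop("'knots' must lie strictly inside 'boundary'")
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary,
                   intercept = FALSE)
  b <- matrix(as.numeric(b), nrow = length(x))
  if (intercept) b <- cbind(1, b)
  b
}

# lag basis evaluated at integer lags 0..max_lag (rows = lags)
lag_basis_matrix <- function(lag_spec) {
  natural_cubic_basis(0:lag_spec$max_lag, knots = lag_spec$knots,
                      boundary = lag_spec$boundary, intercept = TRUE)
}
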