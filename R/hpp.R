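#' Score a heat prevention plan catalogue entry
#'
#' A plan is described by the actions implemented within 8 core elements
#' (the WMO/WHO warning-system guidance elements); each action carries an
#' expert weight between 0 and 2 reflecting its importance in preventing
#' heat-related deaths.  The total score is the simple sum of the weights
#' of all implemented actions.
#'
#' @param actions list (one entry per core element) of numeric action
#'   weight vectors, each weight in `[0, 2]`.
#'
#' @return The total score (numeric scalar).
#' @export
score_hpp <- function(actions) {
  w <- unlist(actions, use.names = FALSE)
  if (is.null(w)) return(0)
  w <- as.numeric(w)
  if (anyNA(w) || any(w < 0 | w > 2))
    stop("action weights must lie in [0, 2]")
  sum(w)
}

#' Classify plans into development terciles
#'
#' Classes 1-3 are defined as terciles of the maximum attainable score
#' of the scoring scheme: cut points at `max_score/3` and
#' `2*max_score/3`, with boundary values assigned upward (a score of
#' exactly `max_score/3` falls in class 2).
#'
#' @param scores numeric vector of per-country total scores.
#' @param max_score maximum attainable score of the scheme (> 0).
#'
#' @return Integer vector of classes (1, 2 or 3).
#' @export
classify_hpp <- function(scores, max_score) {
  if (max_score <= 0) stop("'max_score' must be > 0")
  if (any(scores < 0) || any(scores > max_score))
    stop("scores must lie in [0, max_score]")
  ifelse(scores >= 2 * max_score / 3, 3L,
         ifelse(scores >= max_score / 3, 2L, 1L))
}

#' Subperiod-level intervention indicator
#'
#' Converts a plan's implementation year into a 0/1 indicator per
#' analysis subperiod.  Under the default `"full_coverage"` reading the
#' indicator is 1 from the first subperiod whose entire span is on or
#' after the implementation year (`implementation_year <=
#' start_year`).  Alternative readings: `"strict_after"` requires the
#' whole subperiod to start strictly after the implementation year, and
#' `"any_overlap"` switches the indicator on for any subperiod touching
#' the implementation year.
#'
#' @param implementation_year integer year, or `NA` for "never
#'   implemented" (indicator 0 everywhere).
#' @param start_year,end_year first and last calendar year of the
#'   subperiod (vectors allowed).
#' @param rule indicator reading; see Details.
#'
#' @return Integer 0/1 vector.
#' @export
hpp_indicator <- function(implementation_year, start_year,
                          end_year = start_year + 2L,
                          rule = c("full_coverage", "strict_after",
                                   "any_overlap")) {
  rule <- match.arg(rule)
  if (is.na(implementation_year))
    return(rep(0L, length(start_year)))
  on <- switch(rule,
    full_coverage = implementation_year <= start_year,
    strict_after  = implementation_year < start_year,
    any_overlap   = implementation_year <= end_year)
  as.integer(on)
}

#' Validate and normalise an HPP catalogue table
#'
#' @param catalogue data.frame with columns `country`, `hpp_year`
#'   (integer or NA), `total_score`, `hpp_class`.
#' @return The validated catalogue.
#' @export
validate_catalogue <- function(catalogue) {
  need <- c("country", "hpp_year", "total_score", "hpp_class")
  miss <- setdiff(need, names(catalogue))
  if (length(miss))
    stop("catalogue is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(catalogue$country))
    stop("catalogue has duplicated countries")
  if (any(!catalogue$hpp_class %in% 1:3))
    stop("hpp_class must be 1, 2 or 3")
  catalogue
}
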