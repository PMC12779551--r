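#' A well's longitudinal neurite-length series
#'
#' Container for one well's day-indexed total neurite length. Days at which
#' quantification failed are stored as `NA` so that downstream code can
#' distinguish "failed" from "low signal" (the quality-control rules treat
#' the two differently).
#'
#' @param days Integer vector of acquisition days (calendar day of
#'   differentiation), sorted and strictly increasing.
#' @param length_um Numeric vector of total neurite length in micrometres,
#'   one per day; `NA` marks a day whose quantification failed. Observed
#'   values must be non-negative.
#' @param well_id,donor_id Identifiers.
#' @param group Donor group label, one of `"control"`, `"SALS"`, `"FALS"`,
#'   `"PLS"`.
#' @param treatment Treatment label or `NA` for untreated wells.
#' @param dose_uM Dose in micromolar, or `NA`.
#' @param endpoint_day Experimental endpoint day; defaults to the last
#'   acquisition day.
#'
#' @return An object of class `well_series`: a list with the fields above.
#' @examples
#' ws <- well_series(40:46, c(2e5, 1.9e5, 1.5e5, NA, 9e4, 7e4, 5e4))
#' ws
#' @export
well_series <- function(days, length_um, well_id = "W01", donor_id = NA_character_,
                        group = c("control", "SALS", "FALS", "PLS"),
                        treatment = NA_character_, dose_uM = NA_real_,
                        endpoint_day = max(days)) {
  group <- match.arg(group)
  days <- as.integer(days)
  if (length(days) == 0L) stopf("`days` must be non-empty")
  if (is.unsorted(days, strictly = TRUE))
    stopf("`days` must be sorted and strictly increasing")
  if (length(length_um) != length(days))
    stopf("`length_um` must have one value per day")
  if (any(length_um < 0, na.rm = TRUE))
    stopf("observed neurite lengths must be >= 0")
  if (endpoint_day < max(days))
    stopf("`endpoint_day` must be >= the last acquisition day")
  structure(list(
    well_id = well_id, donor_id = donor_id, group = group,
    treatment = treatment, dose_uM = dose_uM,
    days = days, length_um = as.numeric(length_um),
    endpoint_day = as.integer(endpoint_day)
  ), class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  n_ok <- sum(!is.na(x$length_um))
  cat(sprintf(
    "<well_series> %s donor=%s group=%s treatment=%s\n  days %d-%d (%d observed, %d failed), endpoint day %d\n",
    x$well_id, x$donor_id, x$group,
    ifelse(is.na(x$treatment), "none", x$treatment),
    min(x$days), max(x$days), n_ok, sum(is.na(x$length_um)), x$endpoint_day))
  invisible(x)
}

# Days with successful quantification.
observed_days <- function(series) series$days[!is.na(series$length_um)]
observed_values <- function(series) series$length_um[!is.na(series$length_um)]

assert_has_observations <- function(series) {
  if (!inherits(series, "well_series")) stopf("expected a `well_series` object")
  if (all(is.na(series$length_um)))
    stopf("quantification error: series %s has no non-failed observation",
          series$well_id)
  invisible(series)
}
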