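#' Normalize a well series to its peak
#'
#' Expresses each observation as a percentage of the well's maximum neurite
#' length across time points, so the peak is standardized to 100 for every
#' well. Failed days remain absent.
#'
#' @param series A [well_series()].
#' @return Named numeric vector: day -> percent of peak.
#' @examples
#' ws <- well_series(40:42, c(1e5, 2e5, 1e5))
#' normalize_to_peak(ws)
#' @export
normalize_to_peak <- function(series) {
  assert_has_observations(series)
  v <- observed_values(series)
  if (max(v) <= 0)
    stopf("quantification error: series %s has zero peak", series$well_id)
  setNames(v / max(v) * 100, observed_days(series))
}

#' Normalize a well series to a reference (pretreatment) day
#'
#' Expresses each observation as a percentage of the value on `ref_day`,
#' the convention used to display treated wells relative to their
#' pretreatment state.
#'
#' @param series A [well_series()].
#' @param ref_day Integer reference day; must be observed with a positive
#'   value.
#' @return Named numeric vector: day -> percent of the reference value.
#' @export
normalize_to_reference_day <- function(series, ref_day) {
  assert_has_observations(series)
  i <- match(as.integer(ref_day), series$days)
  if (is.na(i) || is.na(series$length_um[i]))
    stopf("reference error: day %d absent or failed in series %s",
          as.integer(ref_day), series$well_id)
  if (series$length_um[i] <= 0)
    stopf("reference error: day %d value is not positive", as.integer(ref_day))
  setNames(observed_values(series) / series$length_um[i] * 100,
           observed_days(series))
}

# Maximum percent change over all observed day pairs exactly `window` apart.
# direction +1: increase (L2 - L1)/L1; -1: decrease (L1 - L2)/L1.
max_window_rate <- function(series, window, direction) {
  assert_has_observations(series)
  d <- observed_days(series); v <- observed_values(series)
  j <- match(d + window, d)
  ok <- !is.na(j) & v > 0
  if (!any(ok))
    stopf("insufficient-data error: no observed day pair %d days apart",
          window)
  rates <- direction * (v[j[ok]] - v[ok]) / v[ok] * 100
  max(rates)
}

#' Maximum percentage increase in neurite length over a fixed window
#'
#' The neurite growth rate: the maximum percentage increase over `window`
#' days (default 5), taken over all ordered pairs of observed days exactly
#' `window` days apart. Pairs involving a failed day are skipped, not
#' interpolated.
#'
#' @param series A [well_series()].
#' @param window Window in days. The default 5 is the operational
#'   definition; a 2-day variant can be selected for comparability with
#'   48-hour reporting.
#' @return Growth rate in percent (negative for monotone-declining wells).
#' @export
compute_growth_rate <- function(series, window = 5L) {
  max_window_rate(series, as.integer(window), +1)
}

#' Maximum percentage decrease in neurite length over a fixed window
#'
#' The neurite decline rate: the maximum percentage decrease over `window`
#' days (default 2), over all observed day pairs exactly `window` apart.
#'
#' @inheritParams compute_growth_rate
#' @param window Window in days (default 2).
#' @return Decline rate in percent (negative for monotone-growing wells).
#' @export
compute_decline_rate <- function(series, window = 2L) {
  max_window_rate(series, as.integer(window), -1)
}

#' LD50 survival day of a well
#'
#' The day on which the well's neurite length first drops to 50 percent of
#' its peak value: the first observed day at or after the peak day with a
#' value at or below half the peak, or the experimental endpoint if the
#' series never falls that far. The search is restricted to post-peak days
#' ("dropped to 50 percent of its peak"), so early pre-peak dips are
#' ignored. The crossing is reported at the sampled day (no
#' interpolation); set `interpolate = TRUE` for the linear-interpolation
#' variant.
#'
#' @param series A [well_series()].
#' @param endpoint_day Endpoint day (defaults to the series' endpoint).
#' @param interpolate Linearly interpolate the crossing day between the
#'   last day above and the first day at or below 50 percent.
#' @return The LD50 day.
#' @examples
#' ws <- well_series(c(40, 42, 44, 46), c(200, 120, 90, 40))
#' compute_ld50(ws)  # 46: first day at or below 100
#' @export
compute_ld50 <- function(series, endpoint_day = series$endpoint_day,
                         interpolate = FALSE) {
  assert_has_observations(series)
  d <- observed_days(series); v <- observed_values(series)
  peak_i <- which.max(v)
  post <- seq(peak_i, length(d))
  half <- 0.5 * v[peak_i]
  hit <- post[v[post] <= half]
  if (length(hit) == 0L) return(as.numeric(endpoint_day))
  i <- hit[1L]
  if (!interpolate || i == peak_i) return(as.numeric(d[i]))
  # last observed day above half before the crossing
  j <- max(which(d < d[i] & v > half & seq_along(d) >= peak_i))
  d[j] + (v[j] - half) / (v[j] - v[i]) * (d[i] - d[j])
}

#' Quality-control thresholds for well exclusion
#'
#' The three exclusion rules: wells with less than `min_length_um` total
#' neurite length at all time points (low signal); failed quantification in
#' more than `max_failed_fraction` of scheduled time points, not counting
#' days inside `failure_exempt_window` where failure may simply reflect
#' degeneration; and an LD50 before `min_ld50_day`, i.e. before the
#' neurons have matured.
#'
#' @param min_length_um Low-signal threshold in micrometres (default 12500).
#' @param max_failed_fraction Maximum tolerated failed fraction
#'   (default 0.25).
#' @param failure_exempt_window Inclusive day window exempt from the failed
#'   count (default 50-60).
#' @param min_ld50_day Earliest credible LD50 day (default 39).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_length_um = 12500, max_failed_fraction = 0.25,
                      failure_exempt_window = c(50L, 60L),
                      min_ld50_day = 39L) {
  if (min_length_um <= 0 || max_failed_fraction <= 0 || min_ld50_day <= 0)
    stopf("config error: all thresholds must be positive")
  structure(list(min_length_um = min_length_um,
                 max_failed_fraction = max_failed_fraction,
                 failure_exempt_window = as.integer(failure_exempt_window),
                 min_ld50_day = as.integer(min_ld50_day)),
            class = "qc_config")
}

#' Apply the well-exclusion quality-control rules
#'
#' @param series A [well_series()].
#' @param pheno Optionally, a precomputed [well_phenotype()] for the series
#'   (avoids recomputing the LD50).
#' @param cfg A [qc_config()].
#' @return A list with `qc_status` (`"pass"` or `"excluded"`) and
#'   `qc_reasons` (character vector among `"low_signal"`,
#'   `"failed_fraction"`, `"premature_ld50"`; reasons are cumulative).
#' @export
apply_qc <- function(series, pheno = NULL, cfg = qc_config()) {
  reasons <- character(0)
  obs <- series$length_um[!is.na(series$length_um)]
  if (length(obs) == 0L || max(obs) < cfg$min_length_um)
    reasons <- c(reasons, "low_signal")

  w <- cfg$failure_exempt_window
  outside <- series$days < w[1] | series$days > w[2]
  if (any(outside)) {
    frac <- sum(is.na(series$length_um[outside])) / sum(outside)
    if (frac > cfg$max_failed_fraction)
      reasons <- c(reasons, "failed_fraction")
  }

  ld50 <- if (!is.null(pheno)) pheno$ld50_day
  else if (length(obs) > 0L && max(obs) > 0) compute_ld50(series)
  else NA_real_
  if (!is.na(ld50) && ld50 < cfg$min_ld50_day)
    reasons <- c(reasons, "premature_ld50")

  list(qc_status = if (length(reasons)) "excluded" else "pass",
       qc_reasons = reasons)
}

#' Full phenotype of one well
#'
#' Computes the peak, the peak-normalized curve, growth and decline rates,
#' the LD50 day and the QC verdict for one well series.
#'
#' @param series A [well_series()].
#' @param qc A [qc_config()].
#' @param growth_window,decline_window Rate windows in days.
#' @return A list of class `well_phenotype` with fields `well_id`,
#'   `donor_id`, `group`, `treatment`, `dose_uM`, `peak_um`, `peak_day`,
#'   `normalized`, `growth_rate_pct`, `decline_rate_pct`, `ld50_day`,
#'   `qc_status`, `qc_reasons`.
#' @export
well_phenotype <- function(series, qc = qc_config(), growth_window = 5L,
                           decline_window = 2L) {
  assert_has_observations(series)
  v <- observed_values(series); d <- observed_days(series)
  if (max(v) <= 0)
    stopf("quantification error: series %s has zero peak", series$well_id)
  peak_i <- which.max(v)
  growth <- tryCatch(compute_growth_rate(series, growth_window),
                     error = function(e) NA_real_)
  decline <- tryCatch(compute_decline_rate(series, decline_window),
                      error = function(e) NA_real_)
  ld50 <- compute_ld50(series)
  pheno <- list(well_id = series$well_id, donor_id = series$donor_id,
                group = series$group, treatment = series$treatment,
                dose_uM = series$dose_uM,
                peak_um = v[peak_i], peak_day = d[peak_i],
                normalized = normalize_to_peak(series),
                growth_rate_pct = growth, decline_rate_pct = decline,
                ld50_day = ld50)
  verdict <- apply_qc(series, pheno, qc)
  pheno$qc_status <- verdict$qc_status
  pheno$qc_reasons <- verdict$qc_reasons
  structure(pheno, class = "well_phenotype")
}

#' Aggregate passing wells into a donor phenotype
#'
#' Mean and standard error of the LD50 day and of the growth and decline
#' rates over a donor's QC-passing wells. Donors with fewer than
#' `wells_required` passing wells are flagged as excluded rather than
#' summarized.
#'
#' @param phenotypes List of [well_phenotype()] objects for one donor.
#' @param wells_required Minimum number of passing wells (default 3).
#' @return A list of class `donor_phenotype`: `donor_id`, `group`,
#'   `n_wells_pass`, `mean_ld50`, `sem_ld50`, `mean_growth`,
#'   `mean_decline`, and `status` (`"ok"` or `"excluded"`).
#' @export
aggregate_donor <- function(phenotypes, wells_required = 3L) {
  if (length(phenotypes) == 0L) stopf("input error: no well phenotypes")
  pass <- Filter(function(p) identical(p$qc_status, "pass"), phenotypes)
  donor_id <- phenotypes[[1]]$donor_id
  group <- phenotypes[[1]]$group
  if (length(pass) < wells_required) {
    return(structure(list(donor_id = donor_id, group = group,
                          n_wells_pass = length(pass), mean_ld50 = NA_real_,
                          sem_ld50 = NA_real_, mean_growth = NA_real_,
                          mean_decline = NA_real_, status = "excluded"),
                     class = "donor_phenotype"))
  }
  ld <- vapply(pass, `[[`, numeric(1), "ld50_day")
  gr <- vapply(pass, `[[`, numeric(1), "growth_rate_pct")
  dc <- vapply(pass, `[[`, numeric(1), "decline_rate_pct")
  structure(list(donor_id = donor_id, group = group,
                 n_wells_pass = length(pass),
                 mean_ld50 = mean(ld), sem_ld50 = sem(ld),
                 mean_growth = mean(gr, na.rm = TRUE),
                 mean_decline = mean(dc, na.rm = TRUE),
                 status = "ok"),
            class = "donor_phenotype")
}

#' Phenotype every well of a plate and aggregate by donor
#'
#' Convenience wrapper over [well_phenotype()] and [aggregate_donor()] for
#' a list of well series (e.g. the `wells` component of
#' [simulate_plate()]'s output).
#'
#' @param wells Named list of [well_series()] objects.
#' @param qc A [qc_config()].
#' @param wells_required Passed to [aggregate_donor()].
#' @return A list with `well_table` (data frame of per-well phenotypes) and
#'   `donor_table` (data frame of per-donor aggregates, passing donors
#'   only flagged via `status`).
#' @export
phenotype_plate <- function(wells, qc = qc_config(), wells_required = 3L) {
  phenos <- lapply(wells, function(ws)
    tryCatch(well_phenotype(ws, qc), error = function(e) NULL))
  phenos <- Filter(Negate(is.null), phenos)
  well_table <- do.call(rbind, lapply(phenos, function(p) data.frame(
    well = p$well_id, donor = p$donor_id, group = p$group,
    treatment = p$treatment, dose_uM = p$dose_uM,
    peak_um = p$peak_um, peak_day = p$peak_day,
    growth_rate_pct = p$growth_rate_pct,
    decline_rate_pct = p$decline_rate_pct, ld50_day = p$ld50_day,
    qc_status = p$qc_status,
    qc_reasons = paste(p$qc_reasons, collapse = ";"),
    stringsAsFactors = FALSE)))
  rownames(well_table) <- NULL
  key <- paste(well_table$donor, well_table$treatment, sep = "\r")
  donor_table <- do.call(rbind, lapply(split(seq_along(phenos), key),
    function(ix) {
      agg <- aggregate_donor(phenos[ix], wells_required)
      data.frame(donor = agg$donor_id, group = agg$group,
                 treatment = phenos[[ix[1]]]$treatment,
                 n_wells_pass = agg$n_wells_pass, mean_ld50 = agg$mean_ld50,
                 sem_ld50 = agg$sem_ld50, mean_growth = agg$mean_growth,
                 mean_decline = agg$mean_decline, status = agg$status,
                 stringsAsFactors = FALSE)
    }))
  rownames(donor_table) <- NULL
  list(well_table = well_table, donor_table = donor_table)
}
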