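#' A raw ROI fluorescence trace
#'
#' @param samples Numeric vector of fluorescence values (arbitrary units).
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param roi_id Identifier.
#' @return A list of class `fluor_trace`.
#' @export
fluor_trace <- function(samples, sampling_rate = 10, roi_id = "roi1") {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 18L)
    stopf("trace error: at least twice the smoothing window of samples required")
  structure(list(roi_id = roi_id, samples = samples,
                 sampling_rate = sampling_rate),
            class = "fluor_trace")
}

#' Detection configuration for calcium transients
#'
#' @param savgol_window Savitzky-Golay window in samples (odd, default 9,
#'   about 0.9 s at 10 Hz).
#' @param savgol_order Polynomial order (default 3, must be below the
#'   window).
#' @param k_sd Threshold multiplier on the baseline s.d. (default 3).
#' @param baseline_sd_estimator `"robust_mad"` (1.4826 x median absolute
#'   deviation of the smoothed dF/F, which approximates baseline noise
#'   while ignoring events) or `"global_sd"`.
#' @param refractory Minimum samples between successive event onsets
#'   (default 5), preventing double counts from threshold chatter.
#' @param split_merged Within a single supra-threshold epoch, call an
#'   additional event where the smoothed trace falls and rises again by at
#'   least the threshold (default `TRUE`): transients arriving before the
#'   previous one has returned to baseline produce no fresh threshold
#'   crossing and would otherwise be merged.
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(savgol_window = 9L, savgol_order = 3L, k_sd = 3,
                          baseline_sd_estimator = c("robust_mad",
                                                    "global_sd"),
                          refractory = 5L, split_merged = TRUE) {
  baseline_sd_estimator <- match.arg(baseline_sd_estimator)
  if (savgol_window %% 2L == 0L)
    stopf("config error: savgol_window must be odd")
  if (savgol_order >= savgol_window)
    stopf("config error: savgol_order must be below savgol_window")
  if (k_sd <= 0) stopf("config error: k_sd must be > 0")
  structure(list(savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order), k_sd = k_sd,
                 baseline_sd_estimator = baseline_sd_estimator,
                 refractory = as.integer(refractory),
                 split_merged = isTRUE(split_merged)),
            class = "detect_config")
}

#' Relative fluorescence change of a trace
#'
#' dF/F with the baseline F0 taken as the median fluorescence over the
#' whole imaging session: `(F - F0) / F0`. A raw-ratio mode `F / F0` is
#' also available, as both readings are consistent with "ratio of the
#' fluorescence value to the baseline"; the conventional difference form
#' is the default. Either form is invariant to rescaling the raw trace.
#'
#' @param trace A [fluor_trace()].
#' @param mode `"dff"` for `(F - F0)/F0` or `"ratio"` for `F/F0`.
#' @return A list of class `dff_trace` with `dff`, `baseline_f`, `roi_id`,
#'   `sampling_rate`.
#' @export
compute_dff <- function(trace, mode = c("dff", "ratio")) {
  stopifnot(inherits(trace, "fluor_trace"))
  mode <- match.arg(mode)
  f0 <- median(trace$samples)
  if (f0 <= 0) stopf("trace error: non-positive baseline fluorescence")
  dff <- if (mode == "dff") (trace$samples - f0) / f0 else trace$samples / f0
  structure(list(roi_id = trace$roi_id, dff = dff, baseline_f = f0,
                 sampling_rate = trace$sampling_rate, mode = mode,
                 smoothed = FALSE),
            class = "dff_trace")
}

#' Savitzky-Golay smoothing of a dF/F trace
#'
#' Least-squares local polynomial smoothing with the configured window and
#' order; edge samples are handled by the filter's transient polynomial
#' fits within the terminal window. Polynomials of degree at most
#' `savgol_order` pass through unchanged.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param cfg A [detect_config()].
#' @return The smoothed `dff_trace`.
#' @export
smooth_dff <- function(dff, cfg = detect_config()) {
  stopifnot(inherits(dff, "dff_trace"))
  if (cfg$savgol_window >= length(dff$dff))
    stopf("config error: smoothing window must be below the trace length")
  dff$dff_raw <- dff$dff
  dff$dff <- as.numeric(signal::sgolayfilt(dff$dff, p = cfg$savgol_order,
                                           n = cfg$savgol_window))
  dff$smoothed <- TRUE
  dff
}

#' Detect calcium transients by threshold crossing
#'
#' Events are called where the smoothed dF/F crosses upward through
#' `k_sd` times the baseline s.d. (robust MAD estimate by default). An
#' event begins at each upward crossing separated from the previous onset
#' by at least the refractory period; its amplitude is the maximum dF/F
#' between onset and the return below threshold, measured on the
#' unsmoothed dF/F when available so that the filter's peak attenuation
#' does not bias amplitudes.
#'
#' @param dff A smoothed `dff_trace` (see [smooth_dff()]).
#' @param cfg A [detect_config()].
#' @return A list of class `calcium_event_set`: `roi_id`, `event_onsets`
#'   (sample indices, strictly increasing), `event_amplitudes` (dF/F),
#'   `n_events`, `duration_s`, `frequency` (Hz, `n_events / duration`),
#'   `mean_amplitude`, `threshold_used`.
#' @export
detect_events <- function(dff, cfg = detect_config()) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$dff
  sigma <- switch(cfg$baseline_sd_estimator,
                  robust_mad = mad(x),
                  global_sd = sd(x))
  if (!is.finite(sigma) || sigma <= 0)
    stopf(paste("detection error: baseline s.d. estimate is zero;",
                "the trace is degenerate for the configured estimator"))
  thr <- cfg$k_sd * sigma
  lo <- thr / 2
  n <- length(x)
  raw <- dff$dff_raw %||% x
  sigma_raw <- switch(cfg$baseline_sd_estimator,
                      robust_mad = mad(raw), global_sd = sd(raw))
  prom <- cfg$k_sd * sigma_raw

  # hysteresis epochs: an event epoch starts at an upward crossing of the
  # threshold and ends when the trace returns below half the threshold,
  # so that chatter around the threshold during a transient's decay is
  # not called as fresh events
  cand <- integer(0)
  epoch_end <- integer(0)
  i <- 1L
  while (i <= n) {
    if (x[i] > thr && (i == 1L || x[i - 1L] <= thr)) {
      j <- i
      while (j < n && x[j + 1L] >= lo) j <- j + 1L
      cand <- c(cand, i)
      if (cfg$split_merged && j - i >= 2L) {
        # transients arriving before the epoch has returned to baseline
        # produce no new crossing; scan the unsmoothed dF/F (the filter
        # flattens such shoulders) for a dip-and-rise of at least k_sd
        # times its noise s.d.
        run_max <- raw[i]; trough <- raw[i]; trough_at <- i
        for (k in (i + 1L):j) {
          if (raw[k] < trough) { trough <- raw[k]; trough_at <- k }
          if (run_max - trough >= prom && raw[k] - trough >= prom &&
              k > trough_at) {
            cand <- c(cand, trough_at)
            run_max <- raw[k]; trough <- raw[k]; trough_at <- k
          } else if (raw[k] > run_max) run_max <- raw[k]
        }
      }
      epoch_end <- c(epoch_end, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  cand <- sort(unique(cand))
  onsets <- integer(0)
  last <- -Inf
  for (k in cand) {
    if (k - last >= cfg$refractory) { onsets <- c(onsets, k); last <- k }
  }
  amps <- vapply(seq_along(onsets), function(q) {
    i <- onsets[q]
    stop_at <- min(c(onsets[onsets > i] - 1L,
                     epoch_end[epoch_end >= i][1L], n), na.rm = TRUE)
    max(raw[i:stop_at])
  }, numeric(1))
  duration <- length(x) / dff$sampling_rate
  structure(list(roi_id = dff$roi_id, event_onsets = onsets,
                 event_amplitudes = amps, n_events = length(onsets),
                 duration_s = duration,
                 frequency = length(onsets) / duration,
                 mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
                 threshold_used = thr),
            class = "calcium_event_set")
}

#' Run the full detection pipeline on a raw trace
#'
#' Convenience wrapper: [compute_dff()], [smooth_dff()], [detect_events()].
#'
#' @param trace A [fluor_trace()].
#' @param cfg A [detect_config()].
#' @return A `calcium_event_set`.
#' @export
detect_transients <- function(trace, cfg = detect_config()) {
  detect_events(smooth_dff(compute_dff(trace), cfg), cfg)
}

#' Summarize event sets across ROIs
#'
#' Frequency is averaged over ROIs (cells / technical replicates);
#' amplitude is pooled over events, so the two summaries have different
#' n's, matching how frequency and amplitude are conventionally reported.
#'
#' @param event_sets List of `calcium_event_set` objects.
#' @param group Optional group label vector (one per ROI); when given, the
#'   summary is returned per group.
#' @return A data frame with one row per group (or a single `all` row):
#'   `n_rois`, `mean_frequency`, `sem_frequency`, `n_events`,
#'   `mean_amplitude`, `sem_amplitude`.
#' @export
summarize_rois <- function(event_sets, group = NULL) {
  if (length(event_sets) == 0L) stopf("input error: at least one ROI required")
  if (is.null(group)) group <- rep("all", length(event_sets))
  stopifnot(length(group) == length(event_sets))
  do.call(rbind, lapply(split(seq_along(event_sets), group), function(ix) {
    freq <- vapply(event_sets[ix], `[[`, numeric(1), "frequency")
    amps <- unlist(lapply(event_sets[ix], `[[`, "event_amplitudes"))
    data.frame(group = group[ix[1]], n_rois = length(ix),
               mean_frequency = mean(freq), sem_frequency = sem(freq),
               n_events = length(amps),
               mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
               sem_amplitude = sem(amps),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
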