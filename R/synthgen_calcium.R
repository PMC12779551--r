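#' Specification for a synthetic calcium-imaging trace
#'
#' Defaults emulate spontaneous calcium activity recorded at 10 Hz:
#' transients at Poisson-distributed times, each adding an exponentially
#' decaying bump to the relative fluorescence, on top of a constant
#' baseline with additive Gaussian noise.
#'
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param duration Recording duration in seconds.
#' @param event_rate Poisson transient rate in Hz.
#' @param amplitude_scale Peak transient amplitude in dF/F units.
#' @param decay_tau Exponential decay time constant in seconds.
#' @param noise_sd Gaussian noise s.d. in dF/F units.
#' @param baseline_f Baseline fluorescence in arbitrary units.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `calcium_sim_spec`.
#' @export
calcium_sim_spec <- function(sampling_rate = 10, duration = 100,
                             event_rate = 0.2, amplitude_scale = 0.4,
                             decay_tau = 0.5, noise_sd = 0.05,
                             baseline_f = 100, seed = NULL) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(decay_tau, "decay_tau", positive = TRUE)
  if (event_rate < 0) stopf("parameter error: event_rate must be >= 0")
  if (noise_sd < 0) stopf("parameter error: noise_sd must be >= 0")
  assert_scalar_num(baseline_f, "baseline_f", positive = TRUE)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 event_rate = event_rate, amplitude_scale = amplitude_scale,
                 decay_tau = decay_tau, noise_sd = noise_sd,
                 baseline_f = baseline_f, seed = seed),
            class = "calcium_sim_spec")
}

#' Simulate a fluorescence trace with injected calcium transients
#'
#' Transient onset times are drawn from a Poisson process at
#' `spec$event_rate`; each transient adds
#' `amplitude_scale * exp(-dt / decay_tau)` (in dF/F units) from its onset
#' onward. The fluorescence trace is
#' `baseline_f * (1 + signal + noise)`, so the injected amplitudes are
#' expressed on the same relative scale the detector works on.
#'
#' @param spec A [calcium_sim_spec()] object.
#' @param roi_id Identifier attached to the trace.
#' @return A list with `trace` (a [fluor_trace()]), `true_event_times`
#'   (seconds), `true_event_samples` (1-based sample indices) and
#'   `true_amplitudes` (dF/F units).
#' @examples
#' sim <- simulate_calcium_trace(calcium_sim_spec(seed = 3))
#' length(sim$true_event_times)
#' @export
simulate_calcium_trace <- function(spec = calcium_sim_spec(),
                                   roi_id = "roi1") {
  if (!inherits(spec, "calcium_sim_spec"))
    spec <- do.call(calcium_sim_spec, spec)
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  with_seed(spec$seed, {
    n_ev <- rpois(1, spec$event_rate * spec$duration)
    ev_t <- sort(runif(n_ev, 0, spec$duration))
    sig <- numeric(n)
    for (et in ev_t) {
      idx <- which(t >= et)
      sig[idx] <- sig[idx] + spec$amplitude_scale *
        exp(-(t[idx] - et) / spec$decay_tau)
    }
    noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    f <- spec$baseline_f * (1 + sig + noise)
    list(trace = fluor_trace(f, sampling_rate = spec$sampling_rate,
                             roi_id = roi_id),
         true_event_times = ev_t,
         true_event_samples = pmin(floor(ev_t * spec$sampling_rate) + 1L, n),
         true_amplitudes = rep(spec$amplitude_scale, n_ev))
  })
}
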