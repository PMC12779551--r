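test_that("dF/F uses the session median and is scale invariant", {
  const <- fluor_trace(rep(10, 100))
  expect_true(all(compute_dff(const)$dff == 0))

  spike <- fluor_trace(c(rep(10, 99), 20))
  expect_equal(compute_dff(spike)$dff[100], 1.0)

  tr <- simulate_calcium_trace(calcium_sim_spec(seed = 5))$trace
  scaled <- fluor_trace(tr$samples * 7.3, tr$sampling_rate, tr$roi_id)
  expect_equal(compute_dff(scaled)$dff, compute_dff(tr)$dff)

  expect_error(compute_dff(fluor_trace(rep(-5, 100))), "baseline")
  expect_equal(compute_dff(spike, mode = "ratio")$dff[100], 2.0)
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  cfg <- detect_config()
  t <- seq_len(200)
  poly <- 2 + 0.03 * t - 1e-4 * t^2 + 1e-7 * t^3
  d <- compute_dff(fluor_trace(poly + 10))
  sm <- smooth_dff(d, cfg)
  interior <- 5:196
  expect_equal(sm$dff[interior], d$dff[interior], tolerance = 1e-9)

  const <- compute_dff(fluor_trace(rep(5, 100)))
  expect_equal(smooth_dff(const, cfg)$dff, const$dff)

  # variance reduction on white noise
  set.seed(12)
  reduced <- vapply(1:100, function(i) {
    x <- rnorm(200)
    d <- compute_dff(fluor_trace(x + 100))
    var(smooth_dff(d, cfg)$dff) < var(d$dff)
  }, logical(1))
  expect_true(all(reduced))

  expect_error(detect_config(savgol_window = 8), "odd")
  expect_error(detect_config(savgol_order = 9), "below")
})

test_that("single and paired injected transients are detected at their onsets", {
  base <- simulate_calcium_trace(calcium_sim_spec(event_rate = 0,
                                                  noise_sd = 0.05,
                                                  seed = 4))$trace
  n <- length(base$samples)
  bump <- function(at, amp = 0.5, tau = 5)
    100 * amp * exp(-pmax(seq_len(n) - at, 0) / tau) * (seq_len(n) >= at)

  one <- base; one$samples <- one$samples + bump(500)
  ev1 <- detect_transients(one)
  expect_equal(ev1$n_events, 1L)
  expect_lte(abs(ev1$event_onsets - 500), 2)
  expect_lt(abs(ev1$event_amplitudes - 0.5) / 0.5, 0.10)

  two <- base; two$samples <- two$samples + bump(300) + bump(600)
  ev2 <- detect_transients(two)
  expect_equal(ev2$n_events, 2L)
  expect_true(all(abs(ev2$event_onsets - c(300, 600)) <= 2))

  # a slow low-amplitude oscillation never reaches 3x its own robust s.d.
  quiet <- fluor_trace(100 * (1 + 0.01 * sin(seq_len(1000) / 20)))
  ev0 <- detect_transients(quiet)
  expect_equal(ev0$n_events, 0L)
  expect_equal(ev0$frequency, 0)

  expect_error(detect_transients(fluor_trace(rep(3, 100))), "detection error")
})

test_that("event calling is scale invariant and monotone in the threshold", {
  sim <- simulate_calcium_trace(calcium_sim_spec(seed = 21))
  ev_a <- detect_transients(sim$trace)
  scaled <- fluor_trace(sim$trace$samples * 0.31, 10, "r")
  ev_b <- detect_transients(scaled)
  expect_equal(ev_a$event_onsets, ev_b$event_onsets)
  expect_equal(ev_a$event_amplitudes, ev_b$event_amplitudes)
  expect_equal(ev_a$frequency, ev_b$frequency)

  counts <- vapply(c(2, 3, 4, 6, 10), function(k) {
    detect_transients(sim$trace, detect_config(k_sd = k))$n_events
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  # frequency conservation
  expect_equal(ev_a$n_events, ev_a$frequency * ev_a$duration_s)
})

test_that("mean detected frequency recovers the simulated event rate", {
  freqs <- vapply(1:50, function(s) {
    detect_transients(simulate_calcium_trace(
      calcium_sim_spec(event_rate = 0.2, duration = 100,
                       amplitude_scale = 0.4, noise_sd = 0.05,
                       seed = s))$trace)$frequency
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 0.2) / 0.2, 0.15)
})

test_that("ROI summaries average frequency over ROIs and pool amplitudes", {
  mk <- function(n_ev, dur, amps) {
    structure(list(roi_id = "r", event_onsets = seq_len(n_ev),
                   event_amplitudes = amps, n_events = n_ev,
                   duration_s = dur, frequency = n_ev / dur,
                   mean_amplitude = mean(amps), threshold_used = 0.1),
              class = "calcium_event_set")
  }
  one <- summarize_rois(list(mk(5, 50, rep(0.5, 5))))
  expect_equal(one$mean_frequency, 0.1)

  two <- summarize_rois(list(mk(5, 50, rep(0.2, 5)),
                             mk(15, 50, rep(0.4, 15))))
  expect_equal(two$mean_frequency, 0.2)
  expect_equal(two$n_events, 20)
  expect_equal(two$mean_amplitude, mean(c(rep(0.2, 5), rep(0.4, 15))))

  # a doubled event rate is recovered as a doubled frequency
  ratio <- vapply(1:50, function(s) {
    f1 <- detect_transients(simulate_calcium_trace(
      calcium_sim_spec(event_rate = 0.1, seed = s))$trace)$frequency
    f2 <- detect_transients(simulate_calcium_trace(
      calcium_sim_spec(event_rate = 0.2, seed = s + 500))$trace)$frequency
    c(f1, f2)
  }, numeric(2))
  expect_lt(abs(mean(ratio[2, ]) / mean(ratio[1, ]) - 2) / 2, 0.2)
})

test_that("the rank-sum comparison matches exact enumeration and wilcox.test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$method, "exact")

  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)
  expect_equal(sep$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(3:7, 1)); b <- rnorm(sample(3:7, 1))
    expect_equal(compare_groups(a, b)$p, oracle_mw_exact_p(a, b))
    expect_equal(compare_groups(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }

  # large-sample normal approximation against wilcox.test
  a <- rnorm(100); b <- rnorm(100, 0.2)
  expect_equal(compare_groups(a, b)$p,
               wilcox.test(a, b, correct = TRUE)$p.value,
               tolerance = 1e-9)
})
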