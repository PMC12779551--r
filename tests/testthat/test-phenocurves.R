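series_of <- function(map, ...) {
  days <- as.integer(names(map))
  well_series(days, unlist(map, use.names = FALSE), ...)
}

test_that("peak normalization standardizes the peak to 100", {
  s <- series_of(c(`40` = 100000, `41` = 200000, `42` = 100000))
  expect_equal(normalize_to_peak(s), c(`40` = 50, `41` = 100, `42` = 50))

  const <- series_of(c(`40` = 5e4, `41` = 5e4, `42` = 5e4))
  expect_true(all(normalize_to_peak(const) == 100))

  with_fail <- well_series(40:42, c(100, NA, 50))
  norm <- normalize_to_peak(with_fail)
  expect_named(norm, c("40", "42"))
  expect_equal(unname(norm), c(100, 50))

  expect_error(normalize_to_peak(well_series(40:41, c(NA, NA))),
               "quantification error")
  # every normalized curve of a random well peaks at exactly 100
  for (s in 1:20) {
    sim <- simulate_neurite_curve(curve_params(noise_cv = 0.2), 22:60,
                                  seed = s)
    expect_equal(max(normalize_to_peak(sim$series)), 100)
  }
})

test_that("reference-day normalization uses the pretreatment value", {
  s <- series_of(c(`36` = 200000, `40` = 100000))
  norm <- normalize_to_reference_day(s, 36)
  expect_equal(unname(norm[c("36", "40")]), c(100, 50))

  failed_ref <- well_series(36:38, c(NA, 100, 50))
  expect_error(normalize_to_reference_day(failed_ref, 36), "reference error")
})

test_that("growth and decline rates match their defining window maxima", {
  g <- series_of(c(`22` = 100, `27` = 300, `32` = 300))
  expect_equal(compute_growth_rate(g), 200)

  dec <- series_of(c(`22` = 100, `27` = 50))
  expect_equal(compute_growth_rate(dec), -50)

  d <- series_of(c(`45` = 200, `47` = 100))
  expect_equal(compute_decline_rate(d), 50)

  inc <- series_of(c(`45` = 100, `47` = 200))
  expect_equal(compute_decline_rate(inc), -100)

  expect_error(compute_growth_rate(series_of(c(`22` = 1, `24` = 2))),
               "insufficient-data")

  # brute-force enumeration over all day pairs on noiseless curves
  for (s in 1:10) {
    p <- curve_params(noise_cv = 0, dropout_prob = 0,
                      decline_midpoint = 40 + s)
    sim <- simulate_neurite_curve(p, 22:60)
    d <- sim$series$days; v <- sim$series$length_um
    expect_equal(compute_growth_rate(sim$series),
                 oracle_max_rate(d, v, 5, +1))
    expect_equal(compute_decline_rate(sim$series),
                 oracle_max_rate(d, v, 2, -1))
  }
})

test_that("LD50 is the first post-peak day at or below half peak", {
  s <- series_of(c(`40` = 200, `42` = 120, `44` = 90, `46` = 40),
                 endpoint_day = 60)
  expect_equal(compute_ld50(s), 44)  # day 44 is the first at or below 100

  never <- series_of(c(`40` = 200, `45` = 180, `50` = 150),
                     endpoint_day = 60)
  expect_equal(compute_ld50(never), 60)

  early_dip <- series_of(c(`30` = 40, `35` = 100, `40` = 60),
                         endpoint_day = 60)
  expect_equal(compute_ld50(early_dip), 60)

  expect_error(compute_ld50(well_series(40:41, c(NA, NA))),
               "quantification error")

  # interpolation mode crosses between the bracketing days
  interp <- compute_ld50(series_of(c(`40` = 200, `42` = 50)),
                         interpolate = TRUE)
  expect_gt(interp, 40); expect_lt(interp, 42)
})

test_that("the three QC exclusion rules fire with their reason strings", {
  cfg <- qc_config()
  low <- simulate_neurite_curve(
    curve_params(peak_amplitude = 10000, noise_cv = 0, dropout_prob = 0),
    22:60)$series
  v <- apply_qc(low, cfg = cfg)
  expect_equal(v$qc_status, "excluded")
  expect_true("low_signal" %in% v$qc_reasons)

  # 30% of the days outside the exempt window failed, none inside it
  days <- 22:60
  vals <- latent_curve(curve_params(), days)
  fail_idx <- which(days < 50)[seq_len(ceiling(0.3 * sum(days < 50)))]
  vals[fail_idx] <- NA
  frac_fail <- well_series(days, vals)
  v <- apply_qc(frac_fail, cfg = cfg)
  expect_true("failed_fraction" %in% v$qc_reasons)

  premature <- series_of(c(`36` = 2e5, `38` = 0.4 * 2e5, `45` = 0.3 * 2e5))
  v <- apply_qc(premature, cfg = cfg)
  expect_equal(v$qc_reasons, "premature_ld50")

  healthy <- simulate_neurite_curve(
    curve_params(noise_cv = 0, dropout_prob = 0), 22:60)$series
  expect_equal(apply_qc(healthy, cfg = cfg)$qc_status, "pass")
})

test_that("donor aggregation requires three passing wells and reports s.e.m.", {
  mk <- function(ld) {
    p <- well_phenotype(simulate_neurite_curve(
      curve_params(noise_cv = 0, dropout_prob = 0), 22:60)$series)
    p$ld50_day <- ld
    p
  }
  agg <- aggregate_donor(list(mk(44), mk(46), mk(48)))
  expect_equal(agg$mean_ld50, 46)
  expect_equal(agg$sem_ld50, sd(c(44, 46, 48)) / sqrt(3))
  expect_equal(agg$sem_ld50, 1.1547, tolerance = 1e-4)
  expect_equal(agg$status, "ok")

  two <- aggregate_donor(list(mk(44), mk(46)))
  expect_equal(two$status, "excluded")
})

test_that("phenotypes are invariant to rescaling the well", {
  sim <- simulate_neurite_curve(curve_params(noise_cv = 0.15), 22:60,
                                seed = 9)
  s1 <- sim$series
  s2 <- s1
  s2$length_um <- s1$length_um * 3.7
  expect_equal(normalize_to_peak(s1), normalize_to_peak(s2))
  expect_equal(compute_growth_rate(s1), compute_growth_rate(s2))
  expect_equal(compute_decline_rate(s1), compute_decline_rate(s2))
  expect_equal(compute_ld50(s1), compute_ld50(s2))
})

test_that("delaying the decline never decreases the noiseless LD50", {
  lds <- vapply(seq(42, 56, by = 2), function(td) {
    compute_ld50(simulate_neurite_curve(
      curve_params(noise_cv = 0, dropout_prob = 0,
                   decline_midpoint = td), 22:60)$series)
  }, numeric(1))
  expect_true(all(diff(lds) >= 0))
})
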