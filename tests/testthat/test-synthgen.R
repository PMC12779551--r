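test_that("noiseless curves equal the latent curve and agree with the LD50 estimator", {
  p <- curve_params(noise_cv = 0, dropout_prob = 0, peak_amplitude = 2e5,
                    growth_midpoint = 28, growth_scale = 2,
                    decline_midpoint = 48, decline_scale = 2)
  out <- simulate_neurite_curve(p, 22:60, seed = 1)
  expect_equal(out$series$length_um, latent_curve(p, 22:60))
  # daily sampling resolves the analytic crossing to within one day
  expect_lte(abs(compute_ld50(out$series) - out$true_ld50), 1)
})

test_that("a decline that never happens yields the endpoint as true LD50", {
  p <- curve_params(noise_cv = 0, dropout_prob = 0, decline_midpoint = 1000)
  out <- simulate_neurite_curve(p, 22:60, seed = 1)
  expect_equal(out$true_ld50, 60)
  expect_equal(compute_ld50(out$series), 60)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  p <- curve_params(noise_cv = 0.10, dropout_prob = 0)
  latent <- latent_curve(p, 22:60)
  devs <- with_seed(7, vapply(1:500, function(i) {
    obs <- simulate_neurite_curve(p, 22:60)$series$length_um
    (obs - latent) / latent
  }, numeric(39)))
  per_day_sd <- apply(devs, 1, sd)
  expect_true(all(abs(per_day_sd - 0.10) < 0.03))
})

test_that("dropout marks days as failed, not zero", {
  p <- curve_params(noise_cv = 0, dropout_prob = 0.5)
  s <- simulate_neurite_curve(p, 22:60, seed = 3)$series
  expect_gt(sum(is.na(s$length_um)), 0)
  expect_true(all(s$length_um[!is.na(s$length_um)] > 0))
})

test_that("curve parameter validation rejects inconsistent shapes", {
  expect_error(curve_params(decline_midpoint = 20, growth_midpoint = 28),
               "decline_midpoint")
  expect_error(curve_params(noise_cv = 1.2), "noise_cv")
  expect_error(simulate_neurite_curve(curve_params(), integer(0)), "non-empty")
  expect_error(simulate_neurite_curve(curve_params(), c(25, 24)), "sorted")
})

test_that("simulated plates are bit-identical under the same seed", {
  cfg <- sim_plate_config(n_control_donors = 2, n_case_donors = 3,
                          wells_per_donor = 2, seed = 11)
  expect_identical(simulate_plate(cfg), simulate_plate(cfg))
})

test_that("zero donor spread and zero noise give an exact group separation", {
  cfg <- sim_plate_config(n_control_donors = 3, n_case_donors = 3,
                          donor_ld50_mean_control = 50,
                          donor_ld50_mean_case = 44, donor_ld50_sd = 0,
                          noise_cv = 0, dropout_prob = 0, seed = 5)
  plate <- simulate_plate(cfg)
  ctrl <- unique(plate$truth$true_ld50[plate$truth$group == "control"])
  case <- unique(plate$truth$true_ld50[plate$truth$group == "SALS"])
  expect_length(ctrl, 1)
  expect_length(case, 1)
  # 0.01-day truth grid on both sides of the 6-day difference
  expect_lt(abs((ctrl - case) - 6), 0.025)
})

test_that("treatment effects shift the true LD50 of treated wells", {
  cfg <- sim_plate_config(n_control_donors = 1, n_case_donors = 2,
                          wells_per_donor = 2, donor_ld50_sd = 0,
                          noise_cv = 0, dropout_prob = 0,
                          treatment_effects = c(rilu = 4), seed = 2)
  plate <- simulate_plate(cfg)
  tr <- plate$truth
  per_donor <- split(tr, tr$donor)
  for (d in per_donor) {
    shift <- unique(d$true_ld50[d$treatment == "rilu"]) -
      unique(d$true_ld50[d$treatment == "DMSO"])
    expect_lt(abs(shift - 4), 0.1)
  }
})

test_that("a 22-vs-65 donor screen with a 6-day deficit is reliably detected", {
  rejected <- vapply(1:100, function(r) {
    plate <- simulate_plate(sim_plate_config(seed = r))
    ph <- phenotype_plate(plate$wells)
    dt <- ph$donor_table[ph$donor_table$status == "ok", ]
    stats::t.test(dt$mean_ld50[dt$group == "control"],
                  dt$mean_ld50[dt$group == "SALS"])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("rendered images honour their geometry and reject bad geometry", {
  blank <- image_truth(list(), NULL)
  img <- render_image(blank, shape = c(64, 64), psf_sigma = 0,
                      background = 0, noise_model = list(model = "none"))
  expect_true(all(img$pixels == 0))

  one <- image_truth(list(cbind(10:110, 60)), NULL, pixel_size_um = 1)
  expect_equal(one$total_length_um, 100)

  oob <- image_truth(list(cbind(100:200, 60)), NULL)
  expect_error(render_image(oob, shape = c(128, 128)), "outside")
})

test_that("image truth length equals a brute-force point-to-point summation", {
  for (s in 1:5) {
    sim <- suppressWarnings(simulate_image_field(3, 2, shape = c(128, 128),
                                                 seed = s))
    expect_equal(sim$truth$total_length_um,
                 oracle_polyline_length(sim$truth$filament_paths),
                 tolerance = 1e-6)
  }
})

test_that("calcium traces are flat without events and reproducible under seed", {
  spec0 <- calcium_sim_spec(event_rate = 0, noise_sd = 0, seed = 1)
  sim <- simulate_calcium_trace(spec0)
  expect_true(all(sim$trace$samples == spec0$baseline_f))
  expect_length(sim$true_event_times, 0)

  spec <- calcium_sim_spec(seed = 42)
  expect_identical(simulate_calcium_trace(spec), simulate_calcium_trace(spec))
  expect_error(calcium_sim_spec(decay_tau = -1), "decay_tau")
})
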