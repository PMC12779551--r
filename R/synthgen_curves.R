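#' Parameters of the latent neurite growth/decline curve
#'
#' The latent well trajectory is modelled as a product of two logistic
#' sigmoids, `L(t) = A * plogis((t - t_g)/tau_g) * plogis((t_d - t)/tau_d)`:
#' a growth phase as the neurons mature, a plateau, and a degeneration
#' phase. This is the simplest three-phase form consistent with observed
#' motor-neuron neurite trajectories.
#'
#' @param peak_amplitude Asymptotic plateau amplitude `A`, in micrometres of
#'   total neurite length per well (> 0).
#' @param growth_midpoint,growth_scale Day and time-scale (days) of the
#'   growth sigmoid.
#' @param decline_midpoint,decline_scale Day and time-scale (days) of the
#'   decline sigmoid; `decline_midpoint` must exceed `growth_midpoint`.
#' @param noise_cv Coefficient of variation of multiplicative observation
#'   noise (fraction in `[0, 1)`): observed = latent * (1 + eps) with
#'   `eps ~ N(0, noise_cv^2)`.
#' @param dropout_prob Probability that a day's quantification fails and is
#'   recorded as `NA` (fraction in `[0, 1]`).
#'
#' @return A list of class `curve_params`.
#' @examples
#' p <- curve_params(decline_midpoint = 48)
#' simulate_neurite_curve(p, days = 22:60, seed = 1)
#' @export
curve_params <- function(peak_amplitude = 2e5, growth_midpoint = 28,
                         growth_scale = 2, decline_midpoint = 48,
                         decline_scale = 2, noise_cv = 0.10,
                         dropout_prob = 0) {
  assert_scalar_num(peak_amplitude, "peak_amplitude", positive = TRUE)
  assert_scalar_num(growth_scale, "growth_scale", positive = TRUE)
  assert_scalar_num(decline_scale, "decline_scale", positive = TRUE)
  assert_scalar_num(growth_midpoint, "growth_midpoint")
  assert_scalar_num(decline_midpoint, "decline_midpoint")
  if (decline_midpoint <= growth_midpoint)
    stopf("parameter error: decline_midpoint must exceed growth_midpoint")
  if (noise_cv < 0 || noise_cv >= 1)
    stopf("parameter error: noise_cv must be in [0, 1)")
  if (dropout_prob < 0 || dropout_prob > 1)
    stopf("parameter error: dropout_prob must be in [0, 1]")
  structure(list(
    peak_amplitude = peak_amplitude, growth_midpoint = growth_midpoint,
    growth_scale = growth_scale, decline_midpoint = decline_midpoint,
    decline_scale = decline_scale, noise_cv = noise_cv,
    dropout_prob = dropout_prob
  ), class = "curve_params")
}

#' Evaluate the latent neurite-length curve
#'
#' @param params A [curve_params()] object.
#' @param t Numeric vector of days.
#' @return Latent total neurite length in micrometres at each `t`.
#' @export
latent_curve <- function(params, t) {
  params$peak_amplitude *
    stats::plogis((t - params$growth_midpoint) / params$growth_scale) *
    stats::plogis((params$decline_midpoint - t) / params$decline_scale)
}

#' Analytic LD50 of a latent curve
#'
#' The smallest `t >= argmax(L)` with `L(t) <= 0.5 * max(L)`, solved on a
#' 0.01-day grid over `[t_min, t_max]`; `t_max` if the curve never falls to
#' half of its maximum within the range. The search is restricted to
#' post-peak days, matching the semantics of the observed LD50 statistic.
#'
#' @param params A [curve_params()] object.
#' @param t_min,t_max Day range over which the well is observed.
#' @return The true LD50 day (numeric, 0.01-day resolution).
#' @export
analytic_ld50 <- function(params, t_min, t_max) {
  grid <- seq(t_min, t_max, by = 0.01)
  L <- latent_curve(params, grid)
  i_peak <- which.max(L)
  post <- seq(i_peak, length(grid))
  hit <- post[L[post] <= 0.5 * L[i_peak]]
  if (length(hit) == 0L) return(t_max)
  grid[hit[1L]]
}

#' Simulate one well's longitudinal neurite-length series
#'
#' Draws an observed series from the latent growth-plateau-decline curve:
#' multiplicative Gaussian noise with coefficient of variation
#' `params$noise_cv`, and each day independently marked as failed
#' quantification with probability `params$dropout_prob` (failed, not zero:
#' the QC rules treat failed time points distinctly from low signal).
#'
#' @param params A [curve_params()] object.
#' @param days Sorted, strictly increasing integer acquisition days.
#' @param seed Integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream.
#' @inheritParams well_series
#' @return A list with elements `series` (a [well_series()]) and
#'   `true_ld50` (the analytic LD50 of the noiseless latent curve over the
#'   observed day range).
#' @examples
#' out <- simulate_neurite_curve(curve_params(noise_cv = 0), 22:60)
#' out$true_ld50
#' @export
simulate_neurite_curve <- function(params, days, seed = NULL, well_id = "W01",
                                   donor_id = NA_character_,
                                   group = "control",
                                   treatment = NA_character_,
                                   dose_uM = NA_real_) {
  if (!inherits(params, "curve_params")) params <- do.call(curve_params, params)
  if (length(days) == 0L) stopf("input error: `days` must be non-empty")
  if (is.unsorted(days, strictly = TRUE))
    stopf("input error: `days` must be sorted, strictly increasing")
  L <- latent_curve(params, days)
  obs <- with_seed(seed, {
    eps <- if (params$noise_cv > 0) rnorm(length(days), 0, params$noise_cv) else 0
    v <- pmax(L * (1 + eps), 0)
    if (params$dropout_prob > 0)
      v[runif(length(days)) < params$dropout_prob] <- NA_real_
    v
  })
  series <- well_series(days, obs, well_id = well_id, donor_id = donor_id,
                        group = group, treatment = treatment, dose_uM = dose_uM)
  list(series = series,
       true_ld50 = analytic_ld50(params, min(days), max(days)))
}

# Continuous post-peak half-maximum crossing of the latent curve (no grid);
# used to calibrate decline_midpoint against a target LD50.
cont_ld50 <- function(params, t_min, t_max) {
  f <- function(t) latent_curve(params, t)
  opt <- optimize(f, c(t_min, t_max), maximum = TRUE)
  half <- 0.5 * opt$objective
  if (f(t_max) > half) return(t_max)
  uniroot(function(t) f(t) - half, c(opt$maximum, t_max), tol = 1e-6)$root
}

# Find the decline_midpoint giving analytic true LD50 == target (continuous
# solution; the reported truth still uses the 0.01-day grid convention).
calibrate_decline_midpoint <- function(target_ld50, base, t_min, t_max) {
  g <- function(td) {
    p <- base
    p$decline_midpoint <- td
    cont_ld50(p, t_min, t_max) - target_ld50
  }
  lo <- max(base$growth_midpoint + 0.5, target_ld50 - 15)
  hi <- target_ld50 + 15
  if (g(lo) > 0) return(lo)
  if (g(hi) < 0) return(hi)
  uniroot(g, c(lo, hi), tol = 1e-4)$root
}
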