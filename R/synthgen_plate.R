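#' Configuration for a simulated phenotyping / screening plate
#'
#' Defaults emulate the scale of a population-level motor-neuron
#' phenotyping screen: six replicate wells per donor with four image fields
#' per well, daily acquisition from day 22 to day 60, control donors with
#' LD50 centred near day 50 and case donors with an earlier decline.
#'
#' @param n_control_donors,n_case_donors Number of donors per group.
#' @param wells_per_donor Replicate wells per donor and treatment (default 6).
#' @param fields_per_well Image fields per well (default 4).
#' @param day_range Inclusive integer day range of daily acquisition.
#' @param donor_ld50_mean_control,donor_ld50_mean_case Mean true LD50 (days)
#'   of the donor-level distribution per group.
#' @param donor_ld50_sd Between-donor s.d. of true LD50 (days).
#' @param treatment_effects Named numeric vector mapping drug name to its
#'   LD50 shift in days (positive = protective); when non-`NULL`, a `"DMSO"`
#'   reference arm with zero shift is added automatically. `NULL` simulates
#'   an untreated phenotyping plate.
#' @param noise_cv Well-level multiplicative noise CV (see [curve_params()]).
#' @param dropout_prob Per-day probability of failed quantification.
#' @param seed Integer seed; the whole plate is reproducible from it.
#'
#' @return A list of class `sim_plate_config`.
#' @export
sim_plate_config <- function(n_control_donors = 22, n_case_donors = 65,
                             wells_per_donor = 6, fields_per_well = 4,
                             day_range = c(22L, 60L),
                             donor_ld50_mean_control = 50,
                             donor_ld50_mean_case = 44,
                             donor_ld50_sd = 2,
                             treatment_effects = NULL,
                             noise_cv = 0.10, dropout_prob = 0.02,
                             seed = 1L) {
  counts <- c(n_control_donors = n_control_donors,
              n_case_donors = n_case_donors,
              wells_per_donor = wells_per_donor,
              fields_per_well = fields_per_well)
  if (any(counts < 1)) stopf("config error: all counts must be >= 1")
  if (length(day_range) != 2L || day_range[1] >= day_range[2])
    stopf("config error: day_range start must precede end")
  if (!is.null(treatment_effects) &&
      (is.null(names(treatment_effects)) || any(names(treatment_effects) == "")))
    stopf("config error: treatment_effects must be a named numeric vector")
  structure(list(
    n_control_donors = n_control_donors, n_case_donors = n_case_donors,
    wells_per_donor = wells_per_donor, fields_per_well = fields_per_well,
    day_range = as.integer(day_range),
    donor_ld50_mean_control = donor_ld50_mean_control,
    donor_ld50_mean_case = donor_ld50_mean_case,
    donor_ld50_sd = donor_ld50_sd,
    treatment_effects = treatment_effects,
    noise_cv = noise_cv, dropout_prob = dropout_prob,
    seed = as.integer(seed)
  ), class = "sim_plate_config")
}

#' Simulate a phenotyping or drug-screen plate with known ground truth
#'
#' Draws donor-level true LD50s from the configured group distributions,
#' calibrates each donor's latent decline so its analytic LD50 matches the
#' drawn target, shifts the decline midpoint of treated wells by the drug's
#' configured effect, and simulates every replicate well's observed series.
#' Identical seeds give identical output.
#'
#' @param config A [sim_plate_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{layout}{data frame: one row per well (plate, well, donor,
#'       group, treatment, dose_uM, replicate).}
#'     \item{wells}{named list of [well_series()] objects.}
#'     \item{truth}{data frame of per-well analytic true LD50.}
#'     \item{donors}{data frame of per-donor targets and latent parameters.}
#'   }
#' @examples
#' plate <- simulate_plate(sim_plate_config(n_control_donors = 2,
#'   n_case_donors = 2, seed = 7))
#' head(plate$truth)
#' @export
simulate_plate <- function(config = sim_plate_config()) {
  if (!inherits(config, "sim_plate_config"))
    config <- do.call(sim_plate_config, config)
  days <- seq(config$day_range[1], config$day_range[2])
  with_seed(config$seed, {
    donors <- data.frame(
      donor_id = c(sprintf("CTRL%02d", seq_len(config$n_control_donors)),
                   sprintf("CASE%02d", seq_len(config$n_case_donors))),
      group = rep(c("control", "SALS"),
                  c(config$n_control_donors, config$n_case_donors)),
      stringsAsFactors = FALSE)
    mu <- ifelse(donors$group == "control",
                 config$donor_ld50_mean_control, config$donor_ld50_mean_case)
    donors$target_ld50 <- rnorm(nrow(donors), mu, config$donor_ld50_sd)
    # keep targets inside the post-peak observable window
    donors$target_ld50 <- pmin(pmax(donors$target_ld50, 36), max(days))
    donors$peak_amplitude <- 2e5 * runif(nrow(donors), 0.8, 1.2)

    base <- curve_params(noise_cv = config$noise_cv,
                         dropout_prob = config$dropout_prob)
    donors$decline_midpoint <- vapply(seq_len(nrow(donors)), function(i) {
      calibrate_decline_midpoint(donors$target_ld50[i], base,
                                 min(days), max(days))
    }, numeric(1))

    arms <- if (is.null(config$treatment_effects)) {
      data.frame(treatment = NA_character_, shift = 0, dose_uM = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      eff <- config$treatment_effects
      if (!"DMSO" %in% names(eff)) eff <- c(DMSO = 0, eff)
      data.frame(treatment = names(eff), shift = unname(eff),
                 dose_uM = ifelse(names(eff) == "DMSO", NA_real_, 2.5),
                 stringsAsFactors = FALSE)
    }

    layout <- list(); wells <- list(); truth <- list()
    for (i in seq_len(nrow(donors))) {
      for (a in seq_len(nrow(arms))) {
        p <- base
        p$peak_amplitude <- donors$peak_amplitude[i]
        p$decline_midpoint <- donors$decline_midpoint[i] + arms$shift[a]
        for (w in seq_len(config$wells_per_donor)) {
          wid <- sprintf("%s_%s_w%02d", donors$donor_id[i],
                         ifelse(is.na(arms$treatment[a]), "none",
                                arms$treatment[a]), w)
          sim <- simulate_neurite_curve(
            p, days, seed = NULL, well_id = wid,
            donor_id = donors$donor_id[i], group = donors$group[i],
            treatment = arms$treatment[a], dose_uM = arms$dose_uM[a])
          wells[[wid]] <- sim$series
          layout[[wid]] <- data.frame(
            plate = "P1", well = wid, donor = donors$donor_id[i],
            group = donors$group[i], treatment = arms$treatment[a],
            dose_uM = arms$dose_uM[a], replicate = w,
            stringsAsFactors = FALSE)
          truth[[wid]] <- data.frame(
            well = wid, donor = donors$donor_id[i], group = donors$group[i],
            treatment = arms$treatment[a], true_ld50 = sim$true_ld50,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(layout = do.call(rbind, c(layout, list(make.row.names = FALSE))),
         wells = wells,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         donors = donors)
  })
}
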