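#' Days of rescue of a treatment relative to DMSO
#'
#' Treated-group LD50 minus DMSO-group LD50, in days. Positive values mean
#' protection; negative values signal toxicity.
#'
#' @param treated_ld50,dmso_ld50 LD50 days (finite scalars or vectors of
#'   equal length).
#' @return `treated_ld50 - dmso_ld50`.
#' @examples
#' days_of_rescue(55, 50)  # +5
#' @export
days_of_rescue <- function(treated_ld50, dmso_ld50) {
  if (any(!is.finite(treated_ld50)) || any(!is.finite(dmso_ld50)))
    stopf("input error: LD50 values must be finite")
  treated_ld50 - dmso_ld50
}

#' Screen-relative rescue for one donor
#'
#' For primary screens without a dedicated DMSO comparison, each drug's
#' rescue is expressed relative to the average LD50 of all treatments
#' screened in that donor, on the assumption that the average treatment
#' effect is zero. Outputs therefore sum to zero per donor.
#'
#' @param donor_ld50s Named numeric vector: drug -> mean LD50 across the
#'   donor's replicate wells. At least two drugs are required.
#' @param include_reference Whether a `"DMSO"` entry, if present, enters
#'   the averaging denominator (default `FALSE`: DMSO is dropped before
#'   centring).
#' @return Named numeric vector of rescue in days, one per drug.
#' @examples
#' screen_relative_rescue(c(A = 48, B = 50, C = 52))
#' @export
screen_relative_rescue <- function(donor_ld50s, include_reference = FALSE) {
  if (is.null(names(donor_ld50s)) || any(names(donor_ld50s) == ""))
    stopf("input error: donor_ld50s must be a named vector")
  if (!include_reference)
    donor_ld50s <- donor_ld50s[names(donor_ld50s) != "DMSO"]
  if (length(donor_ld50s) < 2L)
    stopf("insufficient-data error: at least two drugs required per donor")
  donor_ld50s - mean(donor_ld50s)
}

#' Cap rescues at the screen's truncation limit
#'
#' Screens are discontinued a fixed number of days after the DMSO
#' controls' LD50, limiting the maximum quantifiable rescue; rescues
#' beyond `cap_days` are capped and flagged as truncated. Truncation is
#' one-sided: negative (toxic) rescues are reported unchanged.
#'
#' @param rescues Numeric vector of rescue values in days.
#' @param cap_days Truncation cap (default 5).
#' @return Data frame with `days_of_rescue` (capped) and `truncated`.
#' @export
truncate_rescues <- function(rescues, cap_days = 5) {
  if (cap_days <= 0) stopf("config error: cap_days must be > 0")
  truncated <- rescues > cap_days
  data.frame(days_of_rescue = pmin(rescues, cap_days),
             truncated = truncated)
}

#' Classify responding donors
#'
#' Fraction of donors whose rescue exceeds `threshold_days`, reported as a
#' percentage rounded to the nearest integer, plus the minimum donor
#' rescue.
#'
#' @param rescues Numeric vector of per-donor rescue values (days).
#' @param threshold_days Strong-rescue threshold (default 10 days).
#' @return A list with `fraction_pct`, `min_rescue` and `responder`
#'   (logical per donor).
#' @examples
#' classify_responders(c(rep(15, 13), 4, 6))  # 13/15 -> 87 percent
#' @export
classify_responders <- function(rescues, threshold_days = 10) {
  if (length(rescues) == 0L) stopf("input error: at least one donor required")
  responder <- rescues > threshold_days
  list(fraction_pct = round(mean(responder) * 100),
       min_rescue = min(rescues),
       responder = responder)
}

#' Fold rescue of a drug relative to a reference treatment
#'
#' Ratio of mean days of rescue, rounded to one decimal (the precision at
#' which combination-versus-monotherapy ratios are reported).
#'
#' @param mean_rescue_drug,mean_rescue_reference Mean rescues in days; the
#'   reference must be positive.
#' @return The fold ratio, one decimal.
#' @examples
#' fold_vs_reference(23.5, 4.7)  # 5.0
#' @export
fold_vs_reference <- function(mean_rescue_drug, mean_rescue_reference) {
  if (mean_rescue_reference <= 0)
    stopf("undefined-fold error: reference rescue must be > 0")
  round(mean_rescue_drug / mean_rescue_reference, 1)
}

#' Summarize a drug screen
#'
#' Per-drug mean rescue and s.e.m. across donors, a Kruskal-Wallis omnibus
#' over drugs, Dunn per-drug comparisons against the reference arm
#' (a `"DMSO"` column if present, otherwise a zero-rescue pseudo-reference
#' of one entry per donor, consistent with screen-relative centring), and
#' population counts: drugs called effective and the percentage of drugs
#' that failed.
#'
#' @param rescue_table Data frame with columns `donor`, `drug`,
#'   `days_of_rescue`.
#' @param effective_drugs Optional character vector of drugs established
#'   as effective; when `NULL`, a drug is called effective if its Dunn
#'   adjusted p-value is below `alpha` and its mean rescue is positive.
#' @param alpha Significance level for the per-drug calls.
#' @return A list of class `screen_summary`: `per_drug` (data frame with
#'   mean, sem, n, z, p_adj, significant, effective), `omnibus`
#'   (Kruskal-Wallis result), `n_tested`, `n_effective`, `percent_failed`.
#' @examples
#' tab <- expand.grid(donor = paste0("d", 1:4), drug = c("A", "B"))
#' tab$days_of_rescue <- c(4, 5, 6, 5, 0, -1, 1, 0)
#' summarize_screen(tab)
#' @export
summarize_screen <- function(rescue_table, effective_drugs = NULL,
                             alpha = 0.05) {
  req <- c("donor", "drug", "days_of_rescue")
  if (!all(req %in% names(rescue_table)))
    stopf("rescue_table must have columns %s", paste(req, collapse = ", "))
  if (nrow(rescue_table) == 0L) stopf("input error: empty rescue table")
  rescue_table$drug <- as.character(rescue_table$drug)

  has_dmso <- "DMSO" %in% rescue_table$drug
  tab <- rescue_table
  if (!has_dmso) {
    donors <- unique(tab$donor)
    tab <- rbind(tab[req],
                 data.frame(donor = donors, drug = "DMSO",
                            days_of_rescue = 0))
  }
  omnibus <- kruskal_wallis(tab$days_of_rescue, tab$drug)
  dunn <- dunn_test(tab$days_of_rescue, tab$drug, ref = "DMSO")

  drugs <- setdiff(unique(rescue_table$drug), "DMSO")
  per_drug <- do.call(rbind, lapply(drugs, function(dr) {
    x <- rescue_table$days_of_rescue[rescue_table$drug == dr]
    data.frame(drug = dr, mean_rescue = mean(x, na.rm = TRUE),
               sem_rescue = sem(x), n_donors = sum(!is.na(x)),
               stringsAsFactors = FALSE)
  }))
  per_drug <- merge(per_drug, dunn, by.x = "drug", by.y = "group",
                    all.x = TRUE, sort = FALSE)
  per_drug$significant <- !is.na(per_drug$p_adj) & per_drug$p_adj < alpha
  per_drug$effective <- if (!is.null(effective_drugs))
    per_drug$drug %in% effective_drugs
  else per_drug$significant & per_drug$mean_rescue > 0
  per_drug <- per_drug[order(-per_drug$mean_rescue), ]
  rownames(per_drug) <- NULL

  n_tested <- nrow(per_drug)
  n_effective <- sum(per_drug$effective)
  structure(list(per_drug = per_drug, omnibus = omnibus,
                 n_tested = n_tested, n_effective = n_effective,
                 percent_failed = round((n_tested - n_effective) /
                                          n_tested * 100)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d drugs tested, %d effective (%d%% failed)\n",
              x$n_tested, x$n_effective, x$percent_failed))
  cat(sprintf("  Kruskal-Wallis H = %.2f (df %d), p = %.3g\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p))
  print(head(x$per_drug, 5))
  invisible(x)
}
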