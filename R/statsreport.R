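#' Kaplan-Meier product-limit survival curve of LD50 days
#'
#' Survival-time analysis treats each unit's LD50 day as its event time.
#' Units whose LD50 equals the experimental endpoint because the 50
#' percent threshold was never reached are entered as censored at the
#' endpoint (event = FALSE): they leave the risk set without contributing
#' an event, the only convention that avoids treating "no degeneration"
#' as degeneration.
#'
#' @param time Numeric vector of LD50 days.
#' @param event Logical vector; `FALSE` marks censoring at the endpoint.
#' @return A data frame of class `km_curve`: `time` (distinct event
#'   times), `n_risk`, `n_event`, `survival`.
#' @examples
#' km_curve(c(40, 45, 50), c(TRUE, TRUE, FALSE))
#' @export
km_curve <- function(time, event = rep(TRUE, length(time))) {
  if (length(time) == 0L) stopf("input error: at least one record required")
  stopifnot(length(event) == length(time))
  if (any(time <= 0)) stopf("input error: LD50 days must be > 0")
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- lapply(ev_times, function(t) {
    n_risk <- sum(time >= t)
    n_event <- sum(time == t & event)
    s <<- s * (1 - n_event / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = n_event, survival = s)
  })
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(time = numeric(0), n_risk = integer(0),
                  n_event = integer(0), survival = numeric(0))
  class(res) <- c("km_curve", "data.frame")
  res
}

#' Two-group log-rank test on LD50 survival
#'
#' The standard log-rank chi-square with one degree of freedom, built from
#' the observed-versus-expected event tabulation at each distinct event
#' time (hypergeometric variance), with a two-sided p-value from the
#' chi-square distribution.
#'
#' @param time_a,event_a,time_b,event_b Event times and event indicators
#'   for the two groups (censored units have `event = FALSE`).
#' @return A list with `chi2`, `p`, `observed` and `expected` (events in
#'   group a).
#' @export
logrank_test <- function(time_a, event_a = rep(TRUE, length(time_a)),
                         time_b, event_b = rep(TRUE, length(time_b))) {
  if (!any(event_a) && !any(event_b))
    stopf("undefined-test error: no events in either group")
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  O <- E <- V <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t); n <- n1 + n2
    d1 <- sum(time_a == t & event_a); d2 <- sum(time_b == t & event_b)
    d <- d1 + d2
    if (n < 1 || d < 1) next
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Correlate an in vitro donor statistic with a clinical variable
#'
#' Pairwise-complete Pearson or Spearman correlation with a two-sided
#' p-value (t approximation for Pearson; exact permutation distribution
#' for Spearman below n = 10, t approximation above). Clinical variables
#' with a log-normal distribution can be log-transformed before
#' correlation.
#'
#' @param x Donor statistic (e.g. mean LD50).
#' @param y Clinical variable (e.g. survival months); must be positive if
#'   `log_transform`.
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform Log-transform `y` first.
#' @return A list of class `corr_result`: `r`, `p`, `n`, `method`,
#'   `transform`.
#' @export
correlate_clinical <- function(x, y, method = c("pearson", "spearman"),
                               log_transform = FALSE) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("input error: at least 3 complete pairs required")
  if (log_transform) {
    if (any(y <= 0)) stopf("input error: log transform requires y > 0")
    y <- log(y)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined-correlation error: constant vector")
  ct <- if (method == "spearman")
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = length(x) < 10))
  else cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 method = method,
                 transform = if (log_transform) "log" else "none"),
            class = "corr_result")
}

#' Compare an in vitro expression signature to a reference profile
#'
#' Spearman correlation of paired log2 fold-change vectors (e.g. the in
#' vitro disease signature against a postmortem tissue profile), with a
#' permutation control built by randomizing the order of the reference
#' fold-change values. The analytic two-sided Spearman p-value is
#' reported alongside the permutation quantile and the null mean.
#'
#' @param logfc_invitro,logfc_reference Paired numeric vectors of log2
#'   fold changes (same length, at least 10 genes).
#' @param n_perm Number of order permutations (at least 100).
#' @param seed Integer seed for the permutation null.
#' @return A list of class `signature_comparison`: `rho`, `p` (analytic),
#'   `p_perm` (two-sided permutation quantile), `null_mean`, `null_rhos`,
#'   `n_perm`, `n_genes`, `seed`.
#' @export
signature_correlation <- function(logfc_invitro, logfc_reference,
                                  n_perm = 1000L, seed = 1L) {
  if (length(logfc_invitro) != length(logfc_reference))
    stopf("input error: fold-change vectors must have the same length")
  n <- length(logfc_invitro)
  if (n < 10L) stopf("input error: at least 10 paired genes required")
  if (n_perm < 100L) stopf("input error: n_perm must be at least 100")
  rho <- cor(logfc_invitro, logfc_reference, method = "spearman")
  p <- suppressWarnings(cor.test(logfc_invitro, logfc_reference,
                                 method = "spearman",
                                 exact = FALSE)$p.value)
  null_rhos <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    cor(logfc_invitro, sample(logfc_reference), method = "spearman")
  }, numeric(1)))
  structure(list(rho = rho, p = p,
                 p_perm = (1 + sum(abs(null_rhos) >= abs(rho))) /
                   (n_perm + 1),
                 null_mean = mean(null_rhos), null_rhos = null_rhos,
                 n_perm = as.integer(n_perm), n_genes = n,
                 seed = as.integer(seed)),
            class = "signature_comparison")
}

# Power of the two-sided (or one-sided) two-sample t test at n per group.
t_test_power <- function(n, d, alpha = 0.05, sides = 2L) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- qt(1 - alpha / sides, df)
  pw <- pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (sides == 2L) pw <- pw + pt(-crit, df, ncp = ncp)
  pw
}

#' Required sample size per group for a two-sample t test
#'
#' Smallest n per group with power at least `1 - beta` at standardized
#' effect size d, found by incrementing n and evaluating noncentral-t
#' power; never below 2.
#'
#' @param effect_size_d Standardized difference d (> 0).
#' @param alpha Type-I error rate (default 0.05).
#' @param beta Type-II error rate (default 0.2, i.e. 80 percent power).
#' @param sides `"two"` (default) or `"one"`.
#' @return Integer n per group.
#' @examples
#' required_sample_size(2)     # 6 per group
#' required_sample_size(10)    # floor of 2
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, beta = 0.2,
                                 sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stopf("parameter error: alpha and beta must be in (0, 1)")
  if (effect_size_d <= 0) stopf("parameter error: d must be > 0")
  k <- if (sides == "two") 2L else 1L
  n <- 2L
  while (t_test_power(n, effect_size_d, alpha, k) < 1 - beta) {
    n <- n + 1L
    if (n > 1e6) stopf("sample size search did not converge")
  }
  n
}
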