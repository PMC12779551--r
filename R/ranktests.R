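# Rank-based tests implemented from their formulas. Base-R equivalents
# (wilcox.test, kruskal.test) serve as independent cross-checks in the
# test suite, not as the implementation.

#' Two-sided Mann-Whitney U test
#'
#' Computes the U statistic for `a` relative to `b`. When the smaller
#' group has at most 8 observations and full enumeration is tractable
#' (at most 200,000 arrangements), the two-sided p-value is computed by
#' exact enumeration of all group assignments of the pooled sample
#' (mid-ranks for ties); otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` selects automatically.
#' @return A list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stopf("input error: both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  small <- min(na, nb)
  can_exact <- small <= 8L && choose(N, small) <= 2e5
  use_exact <- if (is.null(exact)) can_exact else (exact && can_exact)

  if (use_exact) {
    k <- if (na <= nb) na else nb
    combos <- combn(N, k)
    Rk <- colSums(matrix(r[combos], nrow = k))
    Uk <- Rk - k * (k + 1) / 2
    U_ref <- if (na <= nb) U_obs else na * nb - U_obs
    p_lo <- mean(Uk <= U_ref)
    p_hi <- mean(Uk >= U_ref)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U_obs, p = p, method = "exact"))
  }

  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U_obs, p = 1, method = "normal"))
  z <- (U_obs - mu - sign(U_obs - mu) * 0.5) / sqrt(sigma2)
  list(U = U_obs, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Kruskal-Wallis rank-sum omnibus test
#'
#' Tie-corrected H statistic over k groups with a chi-square reference
#' distribution on k - 1 degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return A list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  if (nlevels(groups) < 2L) stopf("at least two groups required")
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  df <- nlevels(groups) - 1L
  list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

#' Dunn's multiple-comparison z tests against a reference group
#'
#' Post-hoc rank comparisons following a Kruskal-Wallis omnibus: each
#' group's mean rank (over the pooled ranking) is compared to the
#' reference group's with the tie-corrected Dunn z statistic, and the
#' two-sided p-values are Bonferroni-adjusted over the number of
#' comparisons.
#'
#' @param values,groups As in [kruskal_wallis()].
#' @param ref Label of the reference group (e.g. the DMSO arm).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame with one row per non-reference group: `group`, `z`,
#'   `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, ref, p_adjust = "bonferroni") {
  groups <- factor(groups)
  if (!ref %in% levels(groups)) stopf("reference group '%s' not found", ref)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  names(n) <- levels(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  others <- setdiff(levels(groups), ref)
  z <- vapply(others, function(g) {
    (Rbar[[g]] - Rbar[[ref]]) /
      sqrt(base_var * (1 / n[[g]] + 1 / n[[ref]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  data.frame(group = others, z = unname(z), p = unname(p),
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE, row.names = NULL)
}
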