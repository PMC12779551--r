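# Independent oracles used to cross-check the package's implementations.
# These are deliberately written against the defining formulas, not by
# calling the code paths they verify.

# Log-rank observed/expected tabulation built directly from the defining
# hypergeometric moments, using a flat per-time data-frame construction.
oracle_logrank_chi2 <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea], tb[eb])))
  tab <- do.call(rbind, lapply(times, function(tt) {
    data.frame(n1 = sum(ta >= tt), n2 = sum(tb >= tt),
               d1 = sum(ta == tt & ea), d2 = sum(tb == tt & eb))
  }))
  tab$n <- tab$n1 + tab$n2
  tab$d <- tab$d1 + tab$d2
  tab <- tab[tab$d > 0 & tab$n > 0, ]
  O <- sum(tab$d1)
  E <- sum(tab$d * tab$n1 / tab$n)
  V <- sum(ifelse(tab$n > 1,
                  tab$d * tab$n1 * tab$n2 * (tab$n - tab$d) /
                    (tab$n^2 * (tab$n - 1)), 0))
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# All 5-day (or k-day) pair rates by full double loop over observed days.
oracle_max_rate <- function(days, values, window, direction) {
  best <- -Inf
  for (i in seq_along(days)) {
    for (j in seq_along(days)) {
      if (days[j] - days[i] == window && !is.na(values[i]) &&
          !is.na(values[j]) && values[i] > 0) {
        r <- direction * (values[j] - values[i]) / values[i] * 100
        if (r > best) best <- r
      }
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled sample into groups, counting tail probabilities of U.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), na)
  U <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(U <= U_obs), mean(U >= U_obs)))
}

# Brute-force polyline arc length by explicit point-to-point summation.
oracle_polyline_length <- function(paths) {
  total <- 0
  for (p in paths) {
    for (i in seq_len(nrow(p) - 1)) {
      total <- total + sqrt(sum((p[i + 1, ] - p[i, ])^2))
    }
  }
  total
}

# Simulated two-sample t-test power at n per group and effect size d.
oracle_sim_power <- function(n, d, reps = 4000, seed = 99) {
  set.seed(seed)
  mean(replicate(reps, stats::t.test(stats::rnorm(n, d), stats::rnorm(n),
                                     var.equal = TRUE)$p.value) < 0.05)
}

# A well series following the latent three-phase curve exactly.
noiseless_series <- function(params, days = 22:60, ...) {
  simulate_neurite_curve(params, days, seed = NULL, ...)
}

# Greedy one-to-one matching of detected onsets to true event samples.
match_events <- function(onsets, truth, tol = 5) {
  used <- rep(FALSE, length(onsets))
  hits <- 0L
  for (t0 in truth) {
    j <- which(!used & abs(onsets - t0) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; hits <- hits + 1L }
  }
  list(hits = hits, false_pos = sum(!used))
}
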