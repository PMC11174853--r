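# Independent brute-force oracles used across the test files. These stay
# deliberately naive (per-position loops, direct summation) so they cannot
# share a defect with the implementation paths they check.

# per-base coverage counter: depth at every integer position
oracle_max_depth <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  positions <- seq(min(starts), max(ends) - 1L)
  max(vapply(positions, function(p) sum(starts <= p & p < ends), integer(1)))
}

# double-loop ECDF difference over the pooled values
oracle_cumulative_shift <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  tot <- 0
  for (x in grid) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    tot <- tot + (fa - fb)
  }
  tot
}

# hypergeometric tail by direct summation over the overlap cell
oracle_fisher_tail <- function(k, n_hits, n_term, n_universe, tail) {
  kmax <- min(n_hits, n_term)
  kmin <- max(0L, n_hits + n_term - n_universe)
  probs <- vapply(kmin:kmax, function(x) {
    choose(n_term, x) * choose(n_universe - n_term, n_hits - x) /
      choose(n_universe, n_hits)
  }, numeric(1))
  ks <- kmin:kmax
  if (tail == "greater") sum(probs[ks >= k]) else sum(probs[ks <= k])
}

# dense grid search over the min-tail objective (mean estimation oracle)
oracle_min_tail_max <- function(counts, trend, grid_n = 4000) {
  lo <- max(min(counts), 1e-3)
  hi <- max(max(counts), lo * 1.001)
  grid <- exp(seq(log(lo), log(hi), length.out = grid_n))
  obj <- vapply(grid, function(m) {
    th <- predict_theta(trend, m)
    min(pmin(pnbinom(counts, mu = m, size = th),
             pnbinom(counts - 1, mu = m, size = th, lower.tail = FALSE)))
  }, numeric(1))
  list(mean = grid[which.max(obj)], objective = max(obj))
}

# the NB-GLM Wald route of the original analysis: stats::glm with the MASS
# negative.binomial family (fixed theta), z from summary(dispersion = 1)
oracle_wald_glm <- function(mean_a, mean_b, df_a, df_b, theta, floor = 8) {
  y <- c(rep(max(mean_a, floor), df_a), rep(max(mean_b, floor), df_b))
  g <- factor(rep(c("a", "b"), c(df_a, df_b)))
  fit <- suppressWarnings(glm(y ~ g, family = MASS::negative.binomial(theta)))
  co <- summary(fit, dispersion = 1)$coefficients
  list(z = co[2, "z value"], p = co[2, "Pr(>|z|)"])
}

# shared small trend used where a known dispersion law is wanted
known_trend <- function() theta_trend(a = 0.5, b = 0.4)
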