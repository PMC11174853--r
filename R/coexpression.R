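# Pair correlation from simulated NB counts.
#
# Because only 4 per-timepoint mean estimates exist per gene, correlation is
# computed on simulated replicate counts: 30 NB2 draws per timepoint mean
# (theta from the dispersion trend), log2-transformed with the >= 8 floor.
# The reported r aggregates the Pearson coefficients of the 16 cross
# pairings of 4 independent simulations per gene, which damps the
# simulation noise of any single draw.

simulate_block <- function(means, trend, draws_per_point, floor) {
  th <- predict_theta(trend, means)
  counts <- stats::rnbinom(length(means) * draws_per_point,
                           mu = rep(means, each = draws_per_point),
                           size = rep(th, each = draws_per_point))
  log2(pmax(counts, floor))
}

#' Simulate a log-scale diurnal expression profile
#'
#' Draws `draws_per_point` NB2 counts for each timepoint mean (theta taken
#' from the trend at that mean), concatenated in timepoint order and
#' log2-transformed with the expression floor.
#'
#' @param means Positive per-timepoint means.
#' @param trend A [theta_trend()].
#' @param draws_per_point Draws per mean (default 30).
#' @param floor Counts below this are raised to it before the log
#'   (default 8).
#' @param seed Optional seed.
#' @return Numeric vector of length `length(means) * draws_per_point`.
#' @export
simulate_profile <- function(means, trend, draws_per_point = 30, floor = 8,
                             seed = NULL) {
  stopifnot(all(means > 0))
  if (!is.null(seed)) set.seed(seed)
  simulate_block(means, trend, draws_per_point, floor)
}

# sign-aware aggregation of the 16 cross-pairing coefficients: a geometric
# mean is undefined for mixed signs, so those fall back to the arithmetic
# mean (see vignette)
aggregate_r <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("all pairings degenerate: r undefined")
  if (all(r >= 0) || all(r <= 0)) {
    sign(sum(r)) * exp(mean(log(pmax(abs(r), .Machine$double.eps))))
  } else {
    mean(r)
  }
}

pair_correlation_engine <- function(means_a, means_b, trend, draws_per_point,
                                    n_sims, floor, seed, use_points = NULL) {
  # canonicalize seed assignment to the lexicographically smaller profile so
  # the aggregate is exactly symmetric in gene order
  swap <- isTRUE(do.call(order, as.data.frame(rbind(means_a, means_b)))[1] == 2)
  first <- if (swap) means_b else means_a
  second <- if (swap) means_a else means_b
  if (!is.null(use_points)) {
    first <- first[use_points]
    second <- second[use_points]
  }
  set.seed(seed)
  sims_1 <- replicate(n_sims, simulate_block(first, trend, draws_per_point,
                                             floor), simplify = FALSE)
  sims_2 <- replicate(n_sims, simulate_block(second, trend, draws_per_point,
                                             floor), simplify = FALSE)
  r16 <- as.vector(outer(seq_len(n_sims), seq_len(n_sims),
                         Vectorize(function(i, j) {
    x <- sims_1[[i]]
    y <- sims_2[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  })))
  list(r = aggregate_r(r16), r_all = r16, n_used = sum(!is.na(r16)),
       n_obs = length(sims_1[[1]]))
}

#' Simulated-count correlation of two genes' diurnal profiles
#'
#' Draws `n_sims` independent simulations per gene ([simulate_profile()]),
#' computes the Pearson r of each of the `n_sims^2` cross pairings, and
#' aggregates by a sign-aware geometric mean (mixed-sign sets fall back to
#' the arithmetic mean). Zero-variance pairings are dropped; an error is
#' raised only if all pairings are degenerate. The aggregate is exactly
#' symmetric in gene order.
#'
#' @param means_a,means_b Per-timepoint mean estimates of the two genes.
#' @param trend A [theta_trend()].
#' @param draws_per_point,floor See [simulate_profile()].
#' @param n_sims Independent simulations per gene (default 4).
#' @param seed Seed (mandatory for reproducibility).
#' @return A `correlation_result` list: `r`, `r_all`, `n_used`, `n_obs`,
#'   `basis`.
#' @export
pair_correlation <- function(means_a, means_b, trend, draws_per_point = 30,
                             n_sims = 4, floor = 8, seed = 1L) {
  stopifnot(length(means_a) == length(means_b), all(means_a > 0),
            all(means_b > 0))
  out <- pair_correlation_engine(means_a, means_b, trend, draws_per_point,
                                 n_sims, floor, seed)
  out$basis <- "diurnal"
  structure(out, class = "correlation_result")
}

#' Per-timepoint simulated-count correlation
#'
#' Same engine and 16-combination aggregation as [pair_correlation()], but
#' simulating only the single tested timepoint's mean (n = `draws_per_point`
#' observations per simulation).
#'
#' @inheritParams pair_correlation
#' @param timepoint Index of the tested timepoint.
#' @return A `correlation_result` with `basis = "per-timepoint"`.
#' @export
timepoint_correlation <- function(means_a, means_b, timepoint, trend,
                                  draws_per_point = 30, n_sims = 4,
                                  floor = 8, seed = 1L) {
  stopifnot(length(means_a) == length(means_b))
  out <- pair_correlation_engine(means_a, means_b, trend, draws_per_point,
                                 n_sims, floor, seed,
                                 use_points = timepoint)
  out$basis <- "per-timepoint"
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result (%s): r = %.3f from %d pairings (%d obs each)\n",
              x$basis, x$r, x$n_used, x$n_obs))
  invisible(x)
}

#' Coexpression call
#'
#' Two genes are coexpressed when their aggregate simulated-count
#' correlation reaches the threshold (default 0.7, i.e. about half of
#' common variance).
#'
#' @param r Aggregate correlation (or a `correlation_result`).
#' @param threshold Default 0.7.
#' @return Logical.
#' @export
coexpression_call <- function(r, threshold = 0.7) {
  if (inherits(r, "correlation_result")) r <- r$r
  if (is.na(r)) stop("r is undefined")
  r >= threshold
}

#' Asymptotic p-value of a Pearson correlation
#'
#' Two-sided p from the t transform `t = r sqrt(n-2) / sqrt(1-r^2)` with
#' `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of observations.
#' @return Two-sided p-value(s).
#' @export
r_asymptotic_p <- function(r, n) {
  stopifnot(n > 2)
  t <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-t, df = n - 2)
}

#' Coexpression preservation and coregulation between lines
#'
#' Given the pairs coexpressed in the reference line, their correlations in
#' the other line, and each gene's cross-line diurnal pattern correlation:
#' the preservation rate is the fraction of reference-line coexpressed
#' pairs also coexpressed in the other line, and the coregulated pairs are
#' the preserved pairs whose *both* members changed their own diurnal
#' pattern drastically between lines (cross-line r below
#' `coregulation_max_r`).
#'
#' @param pairs_a Data frame `gene_a`, `gene_b` of pairs coexpressed in the
#'   reference line.
#' @param r_b Correlations of those same pairs in the other line (same row
#'   order).
#' @param cross_r Named vector: per-gene cross-line diurnal pattern
#'   correlation.
#' @param threshold Coexpression threshold (default 0.7).
#' @param coregulation_max_r Cross-line r below which a gene's pattern is
#'   considered drastically transformed (default 0.5).
#' @return List: `preservation_rate`, `preserved` (logical per pair),
#'   `coregulated` (data frame of coregulated pairs).
#' @export
preservation_and_coregulation <- function(pairs_a, r_b, cross_r,
                                          threshold = 0.7,
                                          coregulation_max_r = 0.5) {
  stopifnot(nrow(pairs_a) == length(r_b))
  preserved <- r_b >= threshold
  rate <- if (nrow(pairs_a) > 0) mean(preserved) else NA_real_
  keep <- preserved &
    cross_r[pairs_a$gene_a] < coregulation_max_r &
    cross_r[pairs_a$gene_b] < coregulation_max_r
  keep[is.na(keep)] <- FALSE
  list(preservation_rate = rate, preserved = preserved,
       coregulated = pairs_a[keep, , drop = FALSE])
}
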