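# Outlier-trimmed mean estimation under the NB2 dispersion trend.
#
# The mean of a small set of replicate counts is estimated by maximizing the
# *lowest* two-sided tail probability of any replicate under NB2(m, theta(m)).
# Replicates whose tail probability at the maximizing mean stays below alpha
# are outliers: the worst one is removed and the mean re-estimated, until all
# retained replicates sit inside the central 1 - alpha mass. With r
# replicates at most r - 2 removals are possible; a gene needing more is
# excluded.

# two-sided tail mass at or beyond count x under NB2(mu, theta)
nb2_tail <- function(x, mu, theta) {
  pmin(stats::pnbinom(x, mu = mu, size = theta),
       stats::pnbinom(x - 1, mu = mu, size = theta, lower.tail = FALSE))
}

# min over counts of the two-sided tail, vectorized over candidate means
min_tail_objective <- function(m, counts, trend) {
  th <- predict_theta(trend, m)
  obj <- rep(Inf, length(m))
  for (x in counts) obj <- pmin(obj, nb2_tail(x, m, th))
  obj
}

# maximize the min-tail objective over [lo, hi]: coarse grid then local refine
maximize_min_tail <- function(counts, trend, grid_n = 64L, tol = 1e-4) {
  lo <- max(min(counts), 1e-3)
  hi <- max(max(counts), lo * (1 + 1e-6))
  if (hi / lo < 1 + 1e-9) {
    return(list(mean = lo, objective = min_tail_objective(lo, counts, trend)))
  }
  grid <- exp(seq(log(lo), log(hi), length.out = grid_n))
  obj <- min_tail_objective(grid, counts, trend)
  k <- which.max(obj)
  bl <- grid[max(k - 1L, 1L)]
  bu <- grid[min(k + 1L, length(grid))]
  opt <- stats::optimize(function(m) min_tail_objective(m, counts, trend),
                         interval = c(bl, bu), maximum = TRUE,
                         tol = tol * grid[k])
  if (opt$objective >= obj[k]) {
    list(mean = opt$maximum, objective = opt$objective)
  } else {
    list(mean = grid[k], objective = obj[k])
  }
}

#' Outlier-trimmed mean estimation for replicate counts
#'
#' Estimates a gene's mean count in one sample group by maximizing the lowest
#' two-sided tail probability of the replicates under `NB2(m, theta(m))`,
#' with theta always taken from the fitted dispersion trend at the candidate
#' mean (never per-gene). Replicates falling outside the central `1 - alpha`
#' probability mass at the maximizing mean are trimmed one at a time (worst
#' first) and the mean re-estimated. Trimming never reduces the retained set
#' below two replicates: a gene that would need that is flagged `excluded`
#' (with three replicates, at most one outlier can ever be removed).
#'
#' The retained-replicate count is the estimate's degrees of freedom: for
#' downstream NB regression the estimated mean is repeated once per retained
#' replicate.
#'
#' @param counts Numeric vector of replicate counts (length >= 2).
#' @param trend A [theta_trend()] mapping mean to dispersion.
#' @param alpha Two-sided tail threshold below which a replicate is an
#'   outlier (default 0.05).
#' @param grid_n,tol Mean-search controls: coarse log-grid size and relative
#'   tolerance of the local refinement.
#' @return A list of class `gene_estimate`: `mean`, `retained` (degrees of
#'   freedom), `outliers` (removed indices), `excluded` (logical),
#'   `objective` (final min-tail probability).
#' @export
estimate_mean_trimmed <- function(counts, trend, alpha = 0.05,
                                  grid_n = 64L, tol = 1e-4) {
  n <- length(counts)
  if (n < 2L) stop("at least 2 replicate counts are required")
  active <- seq_len(n)
  removed <- integer(0)
  repeat {
    fit <- maximize_min_tail(counts[active], trend, grid_n, tol)
    th <- predict_theta(trend, fit$mean)
    tails <- nb2_tail(counts[active], fit$mean, th)
    if (all(tails >= alpha)) {
      return(structure(list(mean = fit$mean, retained = length(active),
                            outliers = removed, excluded = FALSE,
                            objective = fit$objective),
                       class = "gene_estimate"))
    }
    if (length(active) - 1L < 2L) {
      # a further removal would leave < 2 replicates: gene is excluded
      return(structure(list(mean = NA_real_, retained = length(active),
                            outliers = removed, excluded = TRUE,
                            objective = fit$objective),
                       class = "gene_estimate"))
    }
    # greedy removal: among the flagged counts, drop the one whose removal
    # best restores the min-tail objective (the max-min optimum equalizes
    # the extreme tails, so the smallest tail alone cannot identify the
    # outlier)
    flagged <- active[tails < alpha]
    best <- NULL
    best_obj <- -Inf
    for (cand in flagged) {
      rest <- setdiff(active, cand)
      f <- maximize_min_tail(counts[rest], trend, grid_n, tol)
      if (f$objective > best_obj) {
        best_obj <- f$objective
        best <- cand
      }
    }
    removed <- c(removed, best)
    active <- setdiff(active, best)
  }
}

#' @export
print.gene_estimate <- function(x, ...) {
  if (x$excluded) {
    cat("gene_estimate: excluded (", length(x$outliers),
        "outliers removed before exclusion )\n")
  } else {
    cat(sprintf("gene_estimate: mean %.3f, %d replicates retained, %d outlier(s)\n",
                x$mean, x$retained, length(x$outliers)))
  }
  invisible(x)
}

#' Trimmed mean estimation across a whole count matrix
#'
#' Applies [estimate_mean_trimmed()] to every (gene, sample-group) cell of a
#' count matrix, where a sample group is one (line, timepoint) combination.
#'
#' @param cm A [count_matrix()].
#' @param trend A [theta_trend()].
#' @param alpha Outlier threshold, see [estimate_mean_trimmed()].
#' @param genes Optional subset of gene ids (default: all).
#' @return A data frame with one row per (gene, line, timepoint): columns
#'   `gene`, `line`, `timepoint`, `mean`, `df`, `n_outliers`, `excluded`.
#' @export
estimate_means <- function(cm, trend, alpha = 0.05, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(genes)) genes <- rownames(cm$values)
  groups <- unique(cm$samples[, c("line", "timepoint")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    cols <- which(cm$samples$line == groups$line[g] &
                  cm$samples$timepoint == groups$timepoint[g])
    sub <- cm$values[genes, cols, drop = FALSE]
    est <- apply(sub, 1L, estimate_mean_trimmed, trend = trend, alpha = alpha)
    out[[g]] <- data.frame(
      gene = genes,
      line = groups$line[g],
      timepoint = groups$timepoint[g],
      mean = vapply(est, `[[`, numeric(1), "mean"),
      df = vapply(est, `[[`, integer(1), "retained"),
      n_outliers = vapply(est, function(e) length(e$outliers), integer(1)),
      excluded = vapply(est, `[[`, logical(1), "excluded"),
      row.names = NULL
    )
  }
  do.call(rbind, out)
}
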