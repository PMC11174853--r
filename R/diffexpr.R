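# NB-GLM Wald differential expression and timepoint-association tests.
#
# With the dispersion fixed from the abundance trend, the two-group NB GLM
# with log link has a closed-form one-step solution: the group MLEs are the
# group means of the replicated estimated values, and the IRLS weight
# w = mu / (1 + mu / theta) gives Var(log mu_j) = 1 / (n_j * w_j). The Wald
# z statistic for the genotype contrast is the difference of log means over
# its standard error; a two-tailed normal test gives the p-value.

#' Wald test for differential expression between two estimated means
#'
#' Tests H0 that the log fold change between two outlier-trimmed mean
#' estimates is zero, under NB2 with theta taken from the dispersion trend
#' at the average of the tested (replicated) values. Each estimate enters
#' as its mean repeated once per retained replicate, which carries the
#' degrees of freedom. Means below `floor` are raised to `floor` before
#' both the fit and the fold change, so genes expressed in only one line
#' are testable without overestimating the fold change.
#'
#' @param mean_a,mean_b Estimated means (reference line first, so the
#'   returned `log2fc` is b over a).
#' @param df_a,df_b Retained-replicate counts (degrees of freedom).
#' @param trend A [theta_trend()]; ignored if `theta` is given.
#' @param theta Optional fixed theta overriding the trend.
#' @param floor Abundance floor (default 8).
#' @return List: `log2fc`, `p` (two-tailed normal), `z`, `se`, `theta`.
#' @export
wald_test <- function(mean_a, mean_b, df_a = 3L, df_b = 3L, trend = NULL,
                      theta = NULL, floor = 8) {
  fa <- max(mean_a, floor)
  fb <- max(mean_b, floor)
  navg <- (df_a * fa + df_b * fb) / (df_a + df_b)
  if (is.null(theta)) {
    if (is.null(trend)) stop("either trend or theta must be supplied")
    theta <- predict_theta(trend, navg)
  }
  # IRLS weight of the NB log-link GLM at the group mean
  w_a <- fa / (1 + fa / theta)
  w_b <- fb / (1 + fb / theta)
  se <- sqrt(1 / (df_a * w_a) + 1 / (df_b * w_b))
  z <- (log(fb) - log(fa)) / se
  list(log2fc = log2(fb / fa), p = 2 * stats::pnorm(-abs(z)), z = z,
       se = se, theta = theta)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving
#' and elementwise no smaller than the input.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs propagate).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  ord <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(p[ok][ord] * m / seq(m, 1)))
  out[ok[ord]] <- adj
  out
}

#' Call differentially expressed genes
#'
#' Applies the abundance, fold-change and adjusted-significance filters to a
#' table of per-gene Wald results. `status` is UP when the second line is
#' over the first by at least `fc_floor` in log2, DOWN for the mirror case,
#' and NONE otherwise; adjusted p-values are computed per timepoint family.
#'
#' @param results Data frame with columns `gene`, `timepoint`, `mean_a`,
#'   `mean_b`, `log2fc`, `p`.
#' @param abundance_floor A gene must reach this mean in at least one line
#'   (default 8).
#' @param fc_floor Minimum absolute log2 fold change (default 0.9).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return The input with added `p_adj`, `passed_abundance_filter`,
#'   `passed_fc_filter` and `status` columns.
#' @export
call_degs <- function(results, abundance_floor = 8, fc_floor = 0.9,
                      alpha = 0.05) {
  req <- c("gene", "timepoint", "mean_a", "mean_b", "log2fc", "p")
  stopifnot(all(req %in% names(results)))
  out <- results
  out$p_adj <- NA_real_
  for (tp in unique(out$timepoint)) {
    idx <- out$timepoint == tp
    out$p_adj[idx] <- bh_adjust(out$p[idx])
  }
  out$passed_abundance_filter <-
    pmax(out$mean_a, out$mean_b) >= abundance_floor
  out$passed_fc_filter <- abs(out$log2fc) >= fc_floor
  sig <- !is.na(out$p_adj) & out$p_adj < alpha &
    out$passed_abundance_filter & out$passed_fc_filter
  out$status <- ifelse(sig & out$log2fc > 0, "UP",
                       ifelse(sig & out$log2fc < 0, "DOWN", "NONE"))
  out
}

#' Run Wald differential expression over an estimate table
#'
#' Pairs the two lines' trimmed estimates per (gene, timepoint), runs
#' [wald_test()] on every pair with both estimates retained, and calls DEGs.
#' Excluded estimates emit no result.
#'
#' @param estimates Output of [estimate_means()] containing both lines.
#' @param trend A [theta_trend()].
#' @param line_a,line_b Reference and case line labels (defaults: first two
#'   lines present, in order of appearance).
#' @param ... Passed to [call_degs()].
#' @return A DE table (see [call_degs()]).
#' @export
de_table <- function(estimates, trend, line_a = NULL, line_b = NULL, ...) {
  lines <- unique(estimates$line)
  if (is.null(line_a)) line_a <- lines[1]
  if (is.null(line_b)) line_b <- lines[2]
  ea <- estimates[estimates$line == line_a & !estimates$excluded, ]
  eb <- estimates[estimates$line == line_b & !estimates$excluded, ]
  key <- merge(ea, eb, by = c("gene", "timepoint"),
               suffixes = c("_a", "_b"))
  if (nrow(key) == 0L) stop("no testable (gene, timepoint) pairs")
  res <- mapply(function(ma, mb, da, db) {
    w <- wald_test(ma, mb, da, db, trend = trend)
    c(w$log2fc, w$p)
  }, key$mean_a, key$mean_b, key$df_a, key$df_b)
  tab <- data.frame(gene = key$gene, timepoint = key$timepoint,
                    mean_a = key$mean_a, mean_b = key$mean_b,
                    log2fc = res[1, ], p = res[2, ])
  call_degs(tab, ...)
}

#' Time-point-associated expression clustering
#'
#' A gene joins the overexpressed (underexpressed) cluster of timepoint `t`
#' when its expression differs from *each* of the other timepoints by at
#' least `fold` in a consistent direction and all three Wald p-values
#' (theta fixed at the trend value for the gene's mean across all points,
#' BH-adjusted within the gene's triple) fall below `alpha`. Fold changes
#' are computed on floored means.
#'
#' @param estimates Output of [estimate_means()] for one line (or a subset
#'   with a single line).
#' @param trend A [theta_trend()].
#' @param fold Minimum fold difference vs every other point (default 2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param floor Abundance floor applied before fold computation (default 8).
#' @return Data frame `gene`, `timepoint`, `direction`
#'   (overexpressed/underexpressed), one row per cluster membership.
#' @export
timepoint_association <- function(estimates, trend, fold = 2, alpha = 0.05,
                                  floor = 8) {
  stopifnot(length(unique(estimates$line)) == 1L)
  est <- estimates[!estimates$excluded, ]
  tps <- unique(est$timepoint)
  stopifnot(length(tps) >= 2L)
  rows <- list()
  for (g in unique(est$gene)) {
    eg <- est[est$gene == g, ]
    if (nrow(eg) < length(tps)) next  # excluded somewhere: skip gene
    m <- stats::setNames(pmax(eg$mean, floor), eg$timepoint)
    dfs <- stats::setNames(eg$df, eg$timepoint)
    theta <- predict_theta(trend, mean(m))
    for (t in tps) {
      others <- setdiff(tps, t)
      ratio <- m[t] / m[others]
      dir <- if (all(ratio >= fold)) "overexpressed"
             else if (all(ratio <= 1 / fold)) "underexpressed"
             else next
      ps <- vapply(others, function(o) {
        wald_test(m[o], m[t], dfs[o], dfs[t], theta = theta, floor = floor)$p
      }, numeric(1))
      if (all(bh_adjust(ps) < alpha)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, timepoint = t, direction = dir)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), timepoint = character(0),
                      direction = character(0)))
  }
  do.call(rbind, rows)
}

#' Classify how a differential-expression event changes diurnal activity
#'
#' For a DE event at timepoint `t`, compares each line's (log-scale)
#' expression at `t` with its own mean diurnal expression (arithmetic mean
#' of the four floored log2 values). If the case line sits on the opposite
#' side of its diurnal mean from the reference line, the event is an
#' `inversion`; on the same side it is an `enhancement` when farther from
#' the mean and a `weakening` when closer (ties, including sitting exactly
#' on the mean, are weakening).
#'
#' @param cs_profile,ds_profile Per-timepoint mean counts of the reference
#'   and case line (same timepoint order).
#' @param timepoint Index (or name, if profiles are named) of the DE event.
#' @param floor Abundance floor before the log transform (default 8).
#' @return One of `"enhancement"`, `"weakening"`, `"inversion"`.
#' @export
classify_activity_change <- function(cs_profile, ds_profile, timepoint,
                                     floor = 8) {
  stopifnot(length(cs_profile) == length(ds_profile))
  lc <- log2(pmax(cs_profile, floor))
  ld <- log2(pmax(ds_profile, floor))
  dc <- lc[timepoint] - mean(lc)
  dd <- ld[timepoint] - mean(ld)
  if (dc * dd < 0) return("inversion")
  if (abs(dd) > abs(dc)) "enhancement" else "weakening"
}
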