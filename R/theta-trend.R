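#' NB2 mean-variance relationship
#'
#' Quadratic mean-variance function of the NB2 parameterization,
#' `sigma^2 = mu + mu^2 / theta`. As `theta -> Inf` the distribution
#' approaches Poisson and the variance approaches the mean.
#'
#' @param mu Mean count(s), `mu >= 0`.
#' @param theta Shape ("dispersion") parameter(s), strictly positive.
#' @return Numeric vector of variances.
#' @examples
#' nb2_variance(8, 2)    # 40
#' nb2_variance(100, Inf) # 100
#' @export
nb2_variance <- function(mu, theta) {
  if (any(mu < 0)) stop("mu must be nonnegative")
  if (any(theta <= 0)) stop("theta must be strictly positive")
  mu + mu^2 / theta
}

#' Pool genes of similar abundance into dispersion-estimation bins
#'
#' Per-gene dispersion cannot be estimated reliably from 2-3 replicates, so
#' replicate count vectors ("cells": one gene in one sample group) are pooled
#' by their rounded method-of-moments mean. Cells with rounded mean below
#' `min_mean` are excluded; bins with fewer than `min_bin_size` members are
#' merged upward (toward larger means; the last bin merges downward).
#'
#' @param counts A list of numeric vectors, each the replicate counts of one
#'   cell, or a numeric matrix with one cell per row.
#' @param means Optional per-cell means; defaults to the method-of-moments
#'   (arithmetic) mean of each vector.
#' @param min_mean Minimum rounded mean for a cell to enter any bin (default 8).
#' @param min_bin_size Minimum number of member cells per emitted bin
#'   (default 30).
#' @return A list of bins; each bin is a list with `label` (rounded-mean bin
#'   label, the size-weighted label of merged bins), `members` (cell indices),
#'   `counts` (pooled counts), `mus` (per-count cell means) and `n` (member
#'   count).
#' @export
pool_bins <- function(counts, means = NULL, min_mean = 8, min_bin_size = 30) {
  if (is.matrix(counts)) counts <- asplit(counts, 1)
  if (is.null(means)) means <- vapply(counts, mean, numeric(1))
  stopifnot(length(means) == length(counts))
  rmean <- round(means)
  keep <- which(rmean >= min_mean)
  if (length(keep) == 0L) {
    stop("no cells with rounded mean >= ", min_mean,
         "; more (or more highly expressed) genes are required")
  }
  labs <- sort(unique(rmean[keep]))
  groups <- lapply(labs, function(l) keep[rmean[keep] == l])
  sizes <- lengths(groups)
  # merge sparse bins upward; the final bin, if still sparse, merges downward
  i <- 1L
  while (i <= length(groups)) {
    if (sizes[i] >= min_bin_size || length(groups) == 1L) {
      i <- i + 1L
      next
    }
    j <- if (i < length(groups)) i + 1L else i - 1L
    groups[[j]] <- c(groups[[j]], groups[[i]])
    labs[j] <- stats::weighted.mean(c(labs[j], labs[i]), c(sizes[j], sizes[i]))
    sizes[j] <- sizes[j] + sizes[i]
    groups[[i]] <- NULL
    labs <- labs[-i]
    sizes <- sizes[-i]
  }
  if (any(sizes < min_bin_size)) {
    stop("unable to form any bin with >= ", min_bin_size,
         " members; provide more genes")
  }
  lapply(seq_along(groups), function(k) {
    idx <- sort(groups[[k]])
    list(label = labs[k],
         members = idx,
         counts = unlist(counts[idx], use.names = FALSE),
         mus = rep(means[idx], lengths(counts[idx])),
         n = length(idx))
  })
}

#' Maximum-likelihood theta for one bin of pooled counts
#'
#' Fits the NB2 shape parameter by maximum likelihood to the pooled counts of
#' a bin. Each count keeps its own cell mean (supplied via `mu`), so the fit
#' does not assume that all genes in the bin share an expression rate - only
#' that they share the dispersion. Under-dispersed (Poisson-like or constant)
#' bins return the ceiling `cap` rather than diverging.
#'
#' @param bin_counts Integer-valued pooled counts of the bin.
#' @param mu Per-count means; a scalar is recycled. Defaults to the pooled
#'   sample mean.
#' @param cap Ceiling on theta for under-dispersed samples (default 1e6).
#' @return The theta MLE (a positive scalar, at most `cap`).
#' @export
fit_theta_mle <- function(bin_counts, mu = mean(bin_counts), cap = 1e6) {
  stopifnot(length(bin_counts) >= 2L)
  if (length(mu) == 1L) mu <- rep(mu, length(bin_counts))
  stopifnot(length(mu) == length(bin_counts))
  if (stats::var(bin_counts) == 0) return(cap)
  th <- tryCatch(
    suppressWarnings(as.numeric(
      MASS::theta.ml(bin_counts, mu = mu, limit = 50)
    )),
    error = function(e) cap
  )
  if (!is.finite(th) || th <= 0) th <- cap
  min(th, cap)
}

#' Fit the gamma log-linear dispersion trend
#'
#' Regresses the per-bin theta MLEs on the logarithm of the bin mean count
#' under a gamma response with a log link, yielding a smooth positive
#' mean-to-theta function `theta(mu) = exp(a + b * log(mu))`. Predictions
#' outside the observed mean range are clamped to the range boundaries.
#'
#' @param bins A list of bins as returned by [pool_bins()], or a data frame
#'   with columns `mu` and `theta`.
#' @param cap Theta cap forwarded to [fit_theta_mle()].
#' @return A `theta_trend` object: list with `coef` (named `a`, `b`),
#'   `bins` (data frame `mu`, `theta`, `n`) and `range` (valid mean range).
#' @seealso [predict_theta()], [theta_trend()]
#' @export
fit_theta_trend <- function(bins, cap = 1e6) {
  if (is.data.frame(bins)) {
    df <- bins
    if (is.null(df$n)) df$n <- NA_integer_
  } else {
    df <- data.frame(
      mu = vapply(bins, function(b) mean(b$counts), numeric(1)),
      theta = vapply(bins, function(b) fit_theta_mle(b$counts, b$mus, cap),
                     numeric(1)),
      n = vapply(bins, function(b) b$n, numeric(1))
    )
  }
  if (nrow(df) < 2L) stop("at least 2 bins are required to fit a theta trend")
  fit <- stats::glm(theta ~ log(mu), data = df,
                    family = stats::Gamma(link = "log"))
  theta_trend(a = unname(stats::coef(fit)[1]),
              b = unname(stats::coef(fit)[2]),
              range = range(df$mu), bins = df)
}

#' Construct a dispersion trend from known coefficients
#'
#' @param a,b Coefficients of `theta(mu) = exp(a + b * log(mu))`.
#' @param range Valid mean range; predictions are clamped to it.
#' @param bins Optional data frame of the bins behind the fit.
#' @return A `theta_trend` object.
#' @export
theta_trend <- function(a, b, range = c(1e-8, Inf), bins = NULL) {
  structure(list(coef = c(a = a, b = b), range = range, bins = bins),
            class = "theta_trend")
}

#' Predict theta from the fitted dispersion trend
#'
#' @param trend A `theta_trend` object.
#' @param mu Mean count(s) at which to evaluate the trend.
#' @return Positive theta value(s); `mu` outside the valid range is clamped.
#' @export
predict_theta <- function(trend, mu) {
  stopifnot(inherits(trend, "theta_trend"))
  mu <- pmin(pmax(mu, trend$range[1]), trend$range[2])
  exp(trend$coef[["a"]] + trend$coef[["b"]] * log(mu))
}

#' @export
print.theta_trend <- function(x, ...) {
  cat(sprintf("theta_trend: theta(mu) = exp(%.4f %+.4f * log(mu)), mu in [%g, %g]\n",
              x$coef[["a"]], x$coef[["b"]], x$range[1], x$range[2]))
  if (!is.null(x$bins)) cat("  fitted from", nrow(x$bins), "bins\n")
  invisible(x)
}

#' Serialize / deserialize a dispersion trend as JSON
#'
#' @param trend A `theta_trend` object.
#' @param path File path.
#' @return `write_theta_trend` returns `path` invisibly; `read_theta_trend`
#'   returns a `theta_trend`.
#' @export
write_theta_trend <- function(trend, path) {
  stopifnot(inherits(trend, "theta_trend"))
  obj <- list(coef = as.list(trend$coef), range = trend$range)
  if (!is.null(trend$bins)) obj$bins <- trend$bins
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_theta_trend
#' @export
read_theta_trend <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta_trend(a = obj$coef$a, b = obj$coef$b, range = unlist(obj$range),
              bins = if (!is.null(obj$bins)) as.data.frame(obj$bins))
}
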