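test_that("nb2_variance follows the quadratic law", {
  expect_equal(nb2_variance(8, 2), 40)
  expect_equal(nb2_variance(100, Inf), 100)
  expect_equal(nb2_variance(0, 5), 0)
  expect_error(nb2_variance(10, 0), "positive")
  expect_error(nb2_variance(-1, 5), "nonnegative")
})

test_that("pool_bins applies the mean floor and the size floor with upward merging", {
  # 40 cells all at rounded mean 8 -> one bin of 40
  cells <- replicate(40, c(7, 8, 9), simplify = FALSE)
  bins <- pool_bins(cells)
  expect_length(bins, 1)
  expect_equal(bins[[1]]$n, 40)
  # a cell with rounded mean 7 is excluded from all bins
  cells2 <- c(cells, list(c(6, 7, 8)))  # mean 7
  bins2 <- pool_bins(cells2)
  expect_equal(sum(vapply(bins2, function(b) b$n, numeric(1))), 40)
  expect_false(41L %in% unlist(lapply(bins2, `[[`, "members")))
  # 20 cells at mean 8 and 20 at mean 9 -> merged into one bin of 40
  cells3 <- c(replicate(20, c(8, 8, 8), simplify = FALSE),
              replicate(20, c(9, 9, 9), simplify = FALSE))
  bins3 <- pool_bins(cells3)
  expect_length(bins3, 1)
  expect_equal(bins3[[1]]$n, 40)
  # nothing reaches the floor -> error advising more genes
  expect_error(pool_bins(replicate(10, c(8, 8, 8), simplify = FALSE)),
               "more genes")
  expect_error(pool_bins(list(c(1, 2, 1))), "rounded mean")
})

test_that("fit_theta_mle recovers theta and caps under-dispersed bins", {
  set.seed(501)
  x <- rnbinom(5000, mu = 20, size = 5)
  expect_equal(fit_theta_mle(x, mu = 20), 5, tolerance = 0.12)
  # all counts equal -> the cap
  expect_equal(fit_theta_mle(rep(20, 100)), 1e6)
  # Poisson counts -> very large theta
  expect_gte(fit_theta_mle(rpois(10000, 20), mu = 20), 100)
  # invariance to count order
  expect_equal(fit_theta_mle(x, mu = 20), fit_theta_mle(rev(x), mu = 20))
})

test_that("fit_theta_trend recovers a known log-linear trend", {
  set.seed(502)
  mus <- c(8, 16, 32, 64, 128, 256)
  bins <- data.frame(mu = mus, theta = NA_real_)
  for (i in seq_along(mus)) {
    th <- exp(0.5 + 0.4 * log(mus[i]))
    bins$theta[i] <- fit_theta_mle(rnbinom(4000, mu = mus[i], size = th),
                                   mu = mus[i])
  }
  trend <- fit_theta_trend(bins)
  expect_equal(trend$coef[["a"]], 0.5, tolerance = 0.1)
  expect_equal(trend$coef[["b"]], 0.4, tolerance = 0.1)
  # positivity and continuity over the valid range
  grid <- seq(8, 256, length.out = 200)
  pred <- predict_theta(trend, grid)
  expect_true(all(pred > 0))
  expect_lt(max(abs(diff(pred))), 1)
  # clamping outside the range
  expect_equal(predict_theta(trend, 1e-9), predict_theta(trend, 8))
  # flat trend from two equal-theta bins
  flat <- fit_theta_trend(data.frame(mu = c(10, 100), theta = c(6, 6)))
  expect_equal(predict_theta(flat, 10), predict_theta(flat, 100),
               tolerance = 1e-6)
  expect_error(fit_theta_trend(data.frame(mu = 10, theta = 5)), "2 bins")
})

test_that("theta trends serialize to JSON and back", {
  trend <- theta_trend(0.5, 0.4, range = c(8, 512),
                       bins = data.frame(mu = c(8, 512), theta = c(5, 30),
                                         n = c(40, 40)))
  path <- withr::local_tempfile(fileext = ".json")
  write_theta_trend(trend, path)
  back <- read_theta_trend(path)
  expect_equal(back$coef, trend$coef)
  expect_equal(back$range, trend$range)
  expect_equal(predict_theta(back, 77), predict_theta(trend, 77))
})

test_that("estimate_mean_trimmed handles the canonical cases", {
  tr <- known_trend()
  # symmetric case: no outliers, all replicates retained
  e <- estimate_mean_trimmed(c(10, 10, 10), tr)
  expect_false(e$excluded)
  expect_equal(e$retained, 3L)
  expect_length(e$outliers, 0)
  expect_equal(e$mean, 10, tolerance = 0.05)
  # a wild replicate is trimmed; tail of 400 under NB2(~11, theta(11)) < 0.05
  th11 <- predict_theta(tr, 11)
  expect_lt(pnbinom(399, mu = 11, size = th11, lower.tail = FALSE), 0.05)
  e2 <- estimate_mean_trimmed(c(10, 12, 400), tr)
  expect_false(e2$excluded)
  expect_equal(e2$outliers, 3L)
  expect_equal(e2$retained, 2L)
  expect_true(e2$mean >= 10 && e2$mean <= 12)
  # two incompatible outliers with three replicates: excluded
  e3 <- estimate_mean_trimmed(c(1, 100, 10000), tr)
  expect_true(e3$excluded)
  expect_error(estimate_mean_trimmed(5, tr), "at least 2")
})

test_that("trimmed estimation agrees with the dense-grid oracle when no removals occur", {
  tr <- known_trend()
  set.seed(503)
  for (i in 1:25) {
    mu <- 2^runif(1, 3, 8)
    x <- rnbinom(3, mu = mu, size = predict_theta(tr, mu))
    if (length(unique(x)) == 1L) next
    e <- estimate_mean_trimmed(x, tr)
    if (length(e$outliers) > 0 || e$excluded) next
    o <- oracle_min_tail_max(x, tr)
    expect_equal(e$objective, o$objective, tolerance = 1e-3)
    expect_equal(e$mean, o$mean, tolerance = max(0.02 * o$mean, 0.05))
  }
})

test_that("after trimming, retained counts are inside the central mass or the gene is excluded", {
  tr <- known_trend()
  set.seed(504)
  for (i in 1:60) {
    x <- rnbinom(3, mu = 2^runif(1, 3, 9), size = 2)
    if (runif(1) < 0.3) x[sample(3, 1)] <- x[sample(3, 1)] * 20 + 500
    e <- estimate_mean_trimmed(x, tr)
    if (e$excluded) {
      expect_gt(length(e$outliers) + 1, 1)  # a 2nd removal was required
    } else {
      kept <- setdiff(seq_along(x), e$outliers)
      th <- predict_theta(tr, e$mean)
      tails <- pmin(pnbinom(x[kept], mu = e$mean, size = th),
                    pnbinom(x[kept] - 1, mu = e$mean, size = th,
                            lower.tail = FALSE))
      expect_true(all(tails >= 0.05))
    }
  }
})

test_that("estimate_means covers a count matrix cell by cell", {
  tr <- known_trend()
  ds <- generate_dataset(simulation_config(n_genes = 25, seed = 31,
                                           outlier_fraction = 0))
  est <- estimate_means(ds$counts, tr)
  expect_equal(nrow(est), 25 * 8)
  expect_true(all(est$df + est$n_outliers == 3 | est$excluded))
  expect_true(all(est$mean > 0 | est$excluded))
})
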