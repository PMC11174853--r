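test_that("wald_test matches the canonical examples", {
  # null identity
  w <- wald_test(20, 20, 3, 3, theta = 5)
  expect_equal(w$log2fc, 0)
  expect_equal(w$p, 1)
  # plain arithmetic above the floor
  expect_equal(wald_test(8, 16, 3, 3, theta = 5)$log2fc, 1)
  # flooring: means below 8 raised to 8
  expect_equal(wald_test(4, 100, 3, 3, theta = 5)$log2fc, log2(100 / 8),
               tolerance = 1e-9)
  expect_equal(wald_test(2, 7, 3, 3, theta = 5)$log2fc, 0)
  expect_error(wald_test(10, 20, 3, 3), "trend or theta")
})

test_that("closed-form Wald equals the NB-GLM route", {
  set.seed(601)
  for (i in 1:20) {
    ma <- 2^runif(1, 2, 9)
    mb <- 2^runif(1, 2, 9)
    th <- runif(1, 2, 30)
    dfa <- sample(2:3, 1)
    dfb <- sample(2:3, 1)
    w <- wald_test(ma, mb, dfa, dfb, theta = th)
    o <- oracle_wald_glm(ma, mb, dfa, dfb, th)
    expect_equal(w$z, o$z, tolerance = 1e-5)
    expect_equal(w$p, o$p, tolerance = 1e-5)
  }
})

test_that("Wald p-values are uniform under the null", {
  set.seed(602)
  tr <- known_trend()
  n <- 4000
  mu <- 2^runif(n, 4, 9)
  th <- predict_theta(tr, mu)
  ma <- colMeans(matrix(rnbinom(3 * n, mu = rep(mu, each = 3),
                                size = rep(th, each = 3)), nrow = 3))
  mb <- colMeans(matrix(rnbinom(3 * n, mu = rep(mu, each = 3),
                                size = rep(th, each = 3)), nrow = 3))
  ps <- mapply(function(a, b) wald_test(a, b, 3, 3, trend = tr)$p, ma, mb)
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.03)
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("bh_adjust is the BH step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(603)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
  }
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), p.adjust(c(0.5, NA, 0.01), "BH"))
})

test_that("call_degs applies all three filters and is monotone", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"), timepoint = "0h",
    mean_a = c(20, 7, 8, 20), mean_b = c(40, 5, 64, 37),
    log2fc = c(0.85, -1.5, 3, 0.9),
    p = c(1e-6, 1e-6, 1e-6, 1e-6))
  out <- call_degs(tab)
  expect_equal(out$status, c("NONE",  # |lfc| 0.85 < 0.9 despite tiny p
                             "NONE",  # both means < 8
                             "UP", "UP"))
  # tightening thresholds never adds DEGs
  strict_fc <- call_degs(tab, fc_floor = 2)
  expect_true(all(strict_fc$status == "NONE" | out$status != "NONE"))
  strict_a <- call_degs(tab, alpha = 1e-9)
  expect_true(all(strict_a$status == "NONE"))
  down <- call_degs(data.frame(gene = "e", timepoint = "3h", mean_a = 100,
                               mean_b = 20, log2fc = log2(20 / 100),
                               p = 1e-8))
  expect_equal(down$status, "DOWN")
})

test_that("injected DEGs are recovered with high sensitivity", {
  # strong effects at high abundance: |log2fc| = 2, mu >= 64, theta >= 5
  tr <- known_trend()
  set.seed(604)
  n <- 400
  mu <- 2^runif(n, 6, 9)
  lfc <- sample(c(-2, 2), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    tha <- predict_theta(tr, mu[i])
    mub <- mu[i] * 2^lfc[i]
    thb <- predict_theta(tr, mub)
    ea <- estimate_mean_trimmed(rnbinom(3, mu = mu[i], size = tha), tr)
    eb <- estimate_mean_trimmed(rnbinom(3, mu = mub, size = thb), tr)
    if (ea$excluded || eb$excluded) return(NULL)
    w <- wald_test(ea$mean, eb$mean, ea$retained, eb$retained, trend = tr)
    data.frame(gene = i, timepoint = "0h", mean_a = ea$mean, mean_b = eb$mean,
               log2fc = w$log2fc, p = w$p, truth = if (lfc[i] > 0) "UP" else "DOWN")
  })
  tab <- do.call(rbind, rows)
  out <- call_degs(tab)
  expect_gte(mean(out$status == out$truth), 0.8)
})

test_that("timepoint_association detects spiked profiles and rejects weak ones", {
  tr <- theta_trend(log(20), 0)  # theta 20 everywhere: small dispersion
  mk_est <- function(gene, means) {
    data.frame(gene = gene, line = "CS", timepoint = c("0h", "3h", "9h", "16h"),
               mean = means, df = 3L, n_outliers = 0L, excluded = FALSE)
  }
  est <- rbind(mk_est("spike", c(100, 8, 8, 8)),
               mk_est("weak", c(15, 8, 8, 8)),   # 1.875-fold < 2
               mk_est("flat", c(20, 20, 20, 20)),
               mk_est("dip", c(64, 64, 8, 64)))
  cl <- timepoint_association(est, tr)
  expect_equal(cl$direction[cl$gene == "spike"], "overexpressed")
  expect_equal(cl$timepoint[cl$gene == "spike"], "0h")
  expect_false("weak" %in% cl$gene)
  expect_false("flat" %in% cl$gene)
  expect_equal(cl$direction[cl$gene == "dip"], "underexpressed")
  expect_equal(cl$timepoint[cl$gene == "dip"], "9h")
})

test_that("timepoint association recovers injected spikes with high sensitivity", {
  tr <- theta_trend(log(8), 0.2)  # theta >= 5 over the tested range
  set.seed(605)
  n <- 60
  hits <- 0
  for (i in seq_len(n)) {
    spike_at <- sample(4, 1)
    means <- rep(8, 4)
    means[spike_at] <- 100  # 12.5-fold
    counts <- vapply(means, function(m) {
      mean(rnbinom(3, mu = m, size = predict_theta(tr, m)))
    }, numeric(1))
    est <- data.frame(gene = "g", line = "CS",
                      timepoint = c("0h", "3h", "9h", "16h"),
                      mean = counts, df = 3L, n_outliers = 0L,
                      excluded = FALSE)
    cl <- timepoint_association(est, tr)
    if (nrow(cl) == 1 && cl$timepoint == c("0h", "3h", "9h", "16h")[spike_at] &&
        cl$direction == "overexpressed") hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)
})

test_that("classify_activity_change distinguishes the three outcomes", {
  # CS above its diurnal mean, DS below its own -> inversion
  expect_equal(classify_activity_change(c(64, 16, 16, 16), c(16, 64, 64, 64), 1),
               "inversion")
  # same side, farther from the mean -> enhancement
  expect_equal(classify_activity_change(c(32, 16, 16, 16), c(64, 16, 16, 16), 1),
               "enhancement")
  # same side, closer -> weakening
  expect_equal(classify_activity_change(c(64, 16, 16, 16), c(24, 16, 16, 16), 1),
               "weakening")
  # exactly on the DS mean: conservative tie -> weakening
  expect_equal(classify_activity_change(c(64, 16, 16, 16), c(20, 20, 20, 20), 1),
               "weakening")
  # exactly one label for any non-degenerate profile pair
  set.seed(606)
  for (i in 1:20) {
    cs <- 2^runif(4, 3, 8)
    ds <- 2^runif(4, 3, 8)
    lab <- classify_activity_change(cs, ds, sample(4, 1))
    expect_true(lab %in% c("enhancement", "weakening", "inversion"))
  }
})
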