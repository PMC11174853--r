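test_that("config validation rejects degenerate designs", {
  expect_error(simulation_config(n_replicates = 1), "n_replicates")
  expect_error(simulation_config(deg_fraction = 1.2), "deg_fraction")
  expect_error(simulation_config(housekeeping_mean = 0), "housekeeping_mean")
  expect_error(simulation_config(outlier_multiplier = 1), "outlier_multiplier")
  expect_error(simulation_config(paralog_cluster_sizes = c("3" = 0.5)),
               "sum to 1")
  expect_error(simulation_config(ds_global_log2_shift = c(1, 2)),
               "per timepoint")
})

test_that("generation is deterministic and respects the null config", {
  cfg <- simulation_config(n_genes = 120, deg_fraction = 0,
                           outlier_fraction = 0, seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts$values, d2$counts$values)
  expect_true(all(d1$deg_truth == "NONE"))
  # no injected effect: CS and DS true means identical for every gene
  cs <- d1$true_means[, grep("^CS_", colnames(d1$true_means))]
  ds <- d1$true_means[, grep("^DS_", colnames(d1$true_means))]
  expect_equal(unname(cs), unname(ds))
  d3 <- generate_dataset(simulation_config(n_genes = 120, deg_fraction = 0,
                                           outlier_fraction = 0, seed = 12))
  expect_false(identical(d1$counts$values, d3$counts$values))
})

test_that("dataset invariants hold", {
  cfg <- simulation_config(n_genes = 150, deg_fraction = 0.2,
                           outlier_fraction = 0.05, seed = 3)
  ds <- generate_dataset(cfg)
  v <- ds$counts$values
  expect_true(all(v >= 0) && all(v == round(v)))
  # housekeeping gene: identical true mean in every (line, timepoint) cell
  expect_true(all(ds$true_means[ds$housekeeping_gene, ] ==
                    cfg$housekeeping_mean))
  # every gene has exactly one chromosome; clusters are triplets
  expect_identical(names(ds$annotations$chromosome),
                   rownames(v))
  cl <- ds$annotations$paralog
  expect_true(all(table(cl[!is.na(cl)]) == 3))
  # injected DEG truth shows up in the true means
  up <- which(ds$deg_truth == "UP", arr.ind = TRUE)
  i <- up[1, ]
  tp <- colnames(ds$deg_truth)[i[2]]
  expect_equal(
    ds$true_means[i[1], paste0("DS_", tp)] /
      ds$true_means[i[1], paste0("CS_", tp)],
    2^cfg$deg_effect_log2fc)
  # outlier truth marks the multiplied replicates
  expect_equal(sum(ds$outlier_truth), sum(ds$outlier_truth & v >= 0))
})

test_that("counts follow the configured NB2 law (Poisson limit and variance)", {
  # theta -> very large at mu = 100: sample variance across many draws ~ 100
  cfg <- simulation_config(n_genes = 2, lines = "CS", timepoints = "0h",
                           n_replicates = 10000,
                           theta_trend_params = c(a = log(1e6), b = 0),
                           deg_fraction = 0, outlier_fraction = 0,
                           base_mean_log2_mean = log2(100),
                           base_mean_log2_sd = 0,
                           diurnal_amplitude_log2 = 0, seed = 5)
  ds <- generate_dataset(cfg)
  x <- ds$counts$values[2, ]  # gene 1 is the housekeeping gene
  expect_equal(mean(x), 100, tolerance = 0.05)
  expect_equal(var(x), 100, tolerance = 0.1)

  # finite theta: variance matches mu + mu^2/theta
  cfg2 <- simulation_config(n_genes = 2, lines = "CS", timepoints = "0h",
                            n_replicates = 10000,
                            theta_trend_params = c(a = log(5), b = 0),
                            deg_fraction = 0, outlier_fraction = 0,
                            base_mean_log2_mean = log2(64),
                            base_mean_log2_sd = 0,
                            diurnal_amplitude_log2 = 0, seed = 6)
  x2 <- generate_dataset(cfg2)$counts$values[2, ]
  expect_equal(mean(x2), 64, tolerance = 0.05)
  expect_equal(var(x2), nb2_variance(64, 5), tolerance = 0.1)
})

test_that("read alignments round-trip the stored counts", {
  cfg <- simulation_config(n_genes = 12, housekeeping_mean = 40,
                           base_mean_log2_mean = 4, deg_fraction = 0,
                           outlier_fraction = 0, seed = 8)
  ds <- generate_dataset(cfg)
  al <- make_read_alignments(ds, read_length = 75)
  counts <- quantify_alignments(al, genes = rownames(ds$counts$values),
                                samples = colnames(ds$counts$values))
  expect_equal(unname(counts), unname(ds$counts$values))
  # zero counts emit no intervals
  zero <- which(ds$counts$values == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    g <- rownames(ds$counts$values)[zero[1, 1]]
    s <- colnames(ds$counts$values)[zero[1, 2]]
    expect_equal(sum(al$transcript == g & al$sample == s), 0)
  }
  # flagged decoys are excluded by the filters: counts unchanged
  al2 <- make_read_alignments(ds, read_length = 75, flagged_fraction = 0.5)
  expect_gt(sum(!al2$unique | !al2$complete), 0)
  counts2 <- quantify_alignments(al2, genes = rownames(ds$counts$values),
                                 samples = colnames(ds$counts$values))
  expect_equal(counts2, counts)
})

test_that("datasets round-trip through the TSV writers and readers", {
  ds <- generate_dataset(simulation_config(n_genes = 30, seed = 2))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"),
                          hk_gene = ds$housekeeping_gene)
  expect_equal(cm$values, ds$counts$values)
  expect_equal(cm$samples$line, ds$counts$samples$line)
  ann <- read_annotation(file.path(dir, "bp.tsv"))
  expect_equal(ann$gene, ds$annotations$bp$gene)
})
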