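# Synthetic diurnal RNA-seq dataset generator.
#
# Emulates the statistical structure the downstream analysis assumes: NB2
# counts with a mean-dependent dispersion trend, two genotype lines at four
# photoperiod timepoints with three replicates, a stably expressed
# housekeeping gene, injected per-timepoint differential expression with
# signed log2 effects, injected replicate outliers, paralog clusters (by
# default homoeolog triplets) and simple BP / pathway annotation maps.

#' Configuration of the synthetic dataset generator
#'
#' Defaults are the assumed study design: 2 lines (CS parent, DS
#' substitution line) x 4 timepoints (0h, 3h, 9h, 16h) x 3 replicates,
#' an increasing dispersion trend `theta(mu) = exp(0.5 + 0.4 log mu)`,
#' homoeolog triplets, and a housekeeping gene (index 1) with identical true
#' mean in every cell.
#'
#' @param n_genes Number of genes (including the housekeeping gene).
#' @param lines Genotype labels (first = reference line).
#' @param timepoints Timepoint labels, in diurnal order.
#' @param n_replicates Replicates per (line, timepoint); must be >= 2.
#' @param theta_trend_params Named vector `c(a, b)` of the log-linear
#'   mean-to-theta trend `theta(mu) = exp(a + b log mu)`.
#' @param deg_fraction Fraction of genes receiving an injected differential
#'   effect on the second line.
#' @param deg_effect_log2fc Absolute injected log2 fold change (> 0).
#' @param deg_all_timepoint_fraction Fraction of injected DEGs that are
#'   differential at every timepoint (the rest at one random timepoint,
#'   matching the observation that most DEGs are timepoint-specific).
#' @param outlier_fraction Per-replicate probability of an injected outlier.
#' @param outlier_multiplier Multiplier applied to outlier counts (> 1).
#' @param paralog_cluster_sizes Named numeric vector mapping cluster size to
#'   probability (must sum to 1); default all triplets. Size-1 draws leave
#'   genes unclustered.
#' @param housekeeping_mean True mean of the housekeeping gene (> 0).
#' @param n_bp_terms,n_pathway_terms Number of BP / pathway terms to assign.
#' @param n_chromosomes Number of chromosome labels.
#' @param base_mean_log2_mean,base_mean_log2_sd Log2-normal law of per-gene
#'   base means.
#' @param diurnal_amplitude_log2 Maximum per-gene log2 amplitude of the
#'   sinusoidal diurnal modulation (per-gene amplitudes are uniform on
#'   `[0, diurnal_amplitude_log2]`).
#' @param ds_global_log2_shift Per-timepoint log2 shift applied to every
#'   non-housekeeping gene of the second line (a global activity shift;
#'   default none).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              lines = c("CS", "DS"),
                              timepoints = c("0h", "3h", "9h", "16h"),
                              n_replicates = 3,
                              theta_trend_params = c(a = 0.5, b = 0.4),
                              deg_fraction = 0.1,
                              deg_effect_log2fc = 2,
                              deg_all_timepoint_fraction = 0.05,
                              outlier_fraction = 0.01,
                              outlier_multiplier = 8,
                              paralog_cluster_sizes = c("3" = 1),
                              housekeeping_mean = 1000,
                              n_bp_terms = 20,
                              n_pathway_terms = 15,
                              n_chromosomes = 21,
                              base_mean_log2_mean = 5,
                              base_mean_log2_sd = 1.5,
                              diurnal_amplitude_log2 = 1,
                              ds_global_log2_shift = NULL,
                              seed = 1L) {
  if (is.null(ds_global_log2_shift)) {
    ds_global_log2_shift <- rep(0, length(timepoints))
  }
  cfg <- list(n_genes = n_genes, lines = lines, timepoints = timepoints,
              n_replicates = n_replicates,
              theta_trend_params = theta_trend_params,
              deg_fraction = deg_fraction,
              deg_effect_log2fc = deg_effect_log2fc,
              deg_all_timepoint_fraction = deg_all_timepoint_fraction,
              outlier_fraction = outlier_fraction,
              outlier_multiplier = outlier_multiplier,
              paralog_cluster_sizes = paralog_cluster_sizes,
              housekeeping_mean = housekeeping_mean,
              n_bp_terms = n_bp_terms, n_pathway_terms = n_pathway_terms,
              n_chromosomes = n_chromosomes,
              base_mean_log2_mean = base_mean_log2_mean,
              base_mean_log2_sd = base_mean_log2_sd,
              diurnal_amplitude_log2 = diurnal_amplitude_log2,
              ds_global_log2_shift = ds_global_log2_shift,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1)
  if (cfg$n_replicates < 2) stop("n_replicates must be at least 2")
  for (f in c("deg_fraction", "outlier_fraction", "deg_all_timepoint_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$housekeeping_mean <= 0) stop("housekeeping_mean must be positive")
  if (cfg$deg_effect_log2fc <= 0) stop("deg_effect_log2fc must be positive")
  if (cfg$outlier_multiplier <= 1) stop("outlier_multiplier must exceed 1")
  if (abs(sum(cfg$paralog_cluster_sizes) - 1) > 1e-8) {
    stop("paralog_cluster_sizes probabilities must sum to 1")
  }
  if (length(cfg$ds_global_log2_shift) != length(cfg$timepoints)) {
    stop("ds_global_log2_shift must have one value per timepoint")
  }
  invisible(cfg)
}

#' Generate a synthetic diurnal RNA-seq dataset
#'
#' Draws counts from `NB2(mu, theta(mu))` for every (gene, line, timepoint,
#' replicate) cell. Gene 1 is the housekeeping gene: its true mean is
#' identical in all cells. A `deg_fraction` of the remaining genes receive a
#' signed `deg_effect_log2fc` shift on the second line's means at one random
#' timepoint (or all timepoints, for a configurable subset) and are recorded
#' in `deg_truth`; injected replicate outliers are recorded in
#' `outlier_truth`. Identical seeds give bit-identical datasets.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset` list: `counts` ([count_matrix()] of raw
#'   counts), `true_means` / `true_theta` (genes x (line_timepoint)
#'   matrices), `deg_truth` (genes x timepoints character matrix in
#'   UP/DOWN/NONE, direction = second line over first), `outlier_truth`
#'   (genes x samples logical), `annotations` (list: `chromosome`, `bp`,
#'   `pathway`, `paralog`), `housekeeping_gene`, `config`.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  lines <- config$lines
  tps <- config$timepoints
  ntp <- length(tps)
  nrep <- config$n_replicates
  genes <- sprintf("G%05d", seq_len(n))
  hk <- genes[1]

  # per-gene diurnal true-mean profiles (reference line)
  base <- 2^stats::rnorm(n, config$base_mean_log2_mean, config$base_mean_log2_sd)
  amp <- stats::runif(n, 0, config$diurnal_amplitude_log2)
  phase <- stats::runif(n, 0, 2 * pi)
  tt <- 2 * pi * (seq_len(ntp) - 1) / ntp
  prof <- base * 2^(amp * sin(outer(phase, tt, `+`)))  # n x ntp
  prof[1, ] <- config$housekeeping_mean

  cells <- as.vector(outer(tps, lines, function(t, l) paste(l, t, sep = "_")))
  true_means <- matrix(NA_real_, n, length(cells),
                       dimnames = list(genes, cells))
  for (li in seq_along(lines)) {
    for (ti in seq_len(ntp)) {
      true_means[, (li - 1) * ntp + ti] <- prof[, ti]
    }
  }

  # global per-timepoint shift on the second line (housekeeping exempt)
  if (length(lines) >= 2) {
    for (ti in seq_len(ntp)) {
      col <- ntp + ti
      shift <- 2^config$ds_global_log2_shift[ti]
      true_means[-1, col] <- true_means[-1, col] * shift
    }
  }

  # injected per-gene differential effects on the second line
  deg_truth <- matrix("NONE", n, ntp, dimnames = list(genes, tps))
  if (config$deg_fraction > 0 && length(lines) >= 2 && n > 1) {
    n_deg <- round(config$deg_fraction * (n - 1))
    deg_genes <- sample(2:n, n_deg)
    all_tp <- stats::runif(n_deg) < config$deg_all_timepoint_fraction
    sign_up <- sample(c(TRUE, FALSE), n_deg, replace = TRUE)
    for (k in seq_len(n_deg)) {
      g <- deg_genes[k]
      tsel <- if (all_tp[k]) seq_len(ntp) else sample.int(ntp, 1)
      fc <- 2^(config$deg_effect_log2fc * if (sign_up[k]) 1 else -1)
      true_means[g, ntp + tsel] <- true_means[g, ntp + tsel] * fc
      deg_truth[g, tsel] <- if (sign_up[k]) "UP" else "DOWN"
    }
  }

  a <- config$theta_trend_params[["a"]]
  b <- config$theta_trend_params[["b"]]
  true_theta <- exp(a + b * log(true_means))
  # the housekeeping gene is *stably* expressed: near-Poisson dispersion,
  # not the trend value (otherwise normalizing to it would inject its
  # biological-scale noise into every library)
  true_theta[1, ] <- 1e6

  samples <- expand.grid(replicate = seq_len(nrep), timepoint = tps,
                         line = lines, stringsAsFactors = FALSE)
  samples <- samples[, c("line", "timepoint", "replicate")]
  snames <- sprintf("%s_%s_rep%d", samples$line, samples$timepoint,
                    samples$replicate)
  counts <- matrix(0L, n, nrow(samples), dimnames = list(genes, snames))
  outlier_truth <- matrix(FALSE, n, nrow(samples),
                          dimnames = list(genes, snames))
  for (s in seq_len(nrow(samples))) {
    cell <- paste(samples$line[s], samples$timepoint[s], sep = "_")
    mu <- true_means[, cell]
    th <- true_theta[, cell]
    counts[, s] <- stats::rnbinom(n, mu = mu, size = th)
  }
  if (config$outlier_fraction > 0) {
    out <- matrix(stats::runif(length(counts)) < config$outlier_fraction,
                  n, ncol(counts))
    outlier_truth[out] <- TRUE
    counts[out] <- as.integer(round(counts[out] * config$outlier_multiplier))
  }

  annotations <- list(
    chromosome = stats::setNames(
      sprintf("chr%d", sample.int(config$n_chromosomes, n, replace = TRUE)),
      genes),
    bp = if (config$n_bp_terms > 0) {
      data.frame(gene = genes,
                 term = sprintf("BP%02d", sample.int(config$n_bp_terms, n,
                                                     replace = TRUE)))
    } else data.frame(gene = character(0), term = character(0)),
    pathway = if (config$n_pathway_terms > 0) {
      data.frame(gene = genes,
                 term = sprintf("PW%02d", sample.int(config$n_pathway_terms, n,
                                                     replace = TRUE)))
    } else data.frame(gene = character(0), term = character(0)),
    paralog = make_paralog_clusters(genes, config$paralog_cluster_sizes)
  )

  structure(list(counts = count_matrix(counts, samples, hk_gene = hk),
                 true_means = true_means, true_theta = true_theta,
                 deg_truth = deg_truth, outlier_truth = outlier_truth,
                 annotations = annotations, housekeeping_gene = hk,
                 config = config),
            class = "synthetic_dataset")
}

# assign genes to paralog clusters by drawing cluster sizes from the
# configured distribution until the gene pool is exhausted; size-1 draws
# (and the leftover tail) stay unclustered (NA)
make_paralog_clusters <- function(genes, size_dist) {
  sizes <- as.integer(names(size_dist))
  cluster <- stats::setNames(rep(NA_character_, length(genes)), genes)
  pool <- sample(genes)
  cid <- 0L
  while (length(pool) > 0L) {
    k <- sizes[sample.int(length(sizes), 1, prob = size_dist)]
    if (k > length(pool)) break
    if (k > 1L) {
      cid <- cid + 1L
      cluster[pool[seq_len(k)]] <- sprintf("P%05d", cid)
    }
    pool <- pool[-seq_len(k)]
  }
  cluster
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes, %d samples, %d injected DEG cells, seed %d\n",
    nrow(x$counts$values), ncol(x$counts$values),
    sum(x$deg_truth != "NONE"), x$config$seed))
  invisible(x)
}

#' Emit synthetic read alignments reproducing the stored counts
#'
#' For each (gene, sample) with count `c`, emits `c` transcript copies each
#' tiled by non-overlapping `read_length` fragments, so the greatest
#' coverage depth over the synthetic transcript equals `c` exactly
#' (round-trip property with [quantify_alignments()]). A configurable
#' fraction of additional decoy reads is flagged non-unique or incompletely
#' mapped; these must be excluded by the quantification filters.
#'
#' @param dataset A `synthetic_dataset`.
#' @param read_length Fragment length in bp (>= 1).
#' @param transcript_length Synthetic transcript length (>=
#'   `read_length`).
#' @param flagged_fraction Expected number of flagged decoy reads per true
#'   transcript copy.
#' @param genes Optional gene subset (alignment tables grow with total
#'   counts; restrict for large datasets).
#' @param seed Seed for decoy placement.
#' @return Alignment data frame: `transcript`, `sample`, `start`, `end`,
#'   `unique`, `complete` (0-based half-open coordinates).
#' @export
make_read_alignments <- function(dataset, read_length = 75,
                                 transcript_length = 600,
                                 flagged_fraction = 0, genes = NULL,
                                 seed = dataset$config$seed + 1L) {
  stopifnot(read_length >= 1, transcript_length >= read_length)
  set.seed(seed)
  v <- dataset$counts$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  nfrag <- transcript_length %/% read_length
  frag_starts <- (seq_len(nfrag) - 1L) * read_length
  rows <- list()
  for (s in colnames(v)) {
    for (g in rownames(v)) {
      cnt <- v[g, s]
      if (cnt > 0) {
        st <- rep(frag_starts, times = cnt)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = g, sample = s, start = st, end = st + read_length,
          unique = TRUE, complete = TRUE)
      }
      if (flagged_fraction > 0 && cnt > 0) {
        nd <- stats::rpois(1, flagged_fraction * cnt)
        if (nd > 0) {
          st <- sample.int(transcript_length - read_length + 1L, nd,
                           replace = TRUE) - 1L
          nonuniq <- stats::runif(nd) < 0.5
          rows[[length(rows) + 1L]] <- data.frame(
            transcript = g, sample = s, start = st, end = st + read_length,
            unique = !nonuniq, complete = nonuniq)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript = character(0), sample = character(0),
                      start = integer(0), end = integer(0),
                      unique = logical(0), complete = logical(0)))
  }
  do.call(rbind, rows)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Writes `counts.tsv` (readable by [read_count_matrix()]), annotation maps
#' (`chromosome.tsv`, `bp.tsv`, `pathway.tsv`, `paralog.tsv`; 2-column
#' gene/term TSVs) and truth tables (`deg_truth.tsv`, `outlier_truth.tsv`).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(dataset$counts, file.path(dir, "counts.tsv"))
  ann <- dataset$annotations
  utils::write.table(data.frame(gene = names(ann$chromosome),
                                chromosome = unname(ann$chromosome)),
                     file.path(dir, "chromosome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$bp, file.path(dir, "bp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$pathway, file.path(dir, "pathway.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(ann$paralog),
                                cluster = unname(ann$paralog)),
                     file.path(dir, "paralog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dt <- data.frame(gene = rownames(dataset$deg_truth), dataset$deg_truth,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(dt, file.path(dir, "deg_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ot <- data.frame(gene = rownames(dataset$outlier_truth),
                   dataset$outlier_truth, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(ot, file.path(dir, "outlier_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
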