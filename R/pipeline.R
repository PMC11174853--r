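# End-to-end pipeline orchestration and report computations.

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Defaults mirror the
#' analysis constants used throughout the package: abundance floor 8,
#' |log2FC| >= 0.9, alpha 0.05, 30 draws per point, set size >= 100,
#' permutation floor 1e-4, coexpression r >= 0.7, coregulation cross-line
#' r < 0.5, 2-fold timepoint association.
#'
#' @param synthetic A [simulation_config()], or `NULL` to read counts from
#'   `counts_path`.
#' @param counts_path TSV of counts (see [read_count_matrix()]) when
#'   `synthetic` is `NULL`.
#' @param hk_gene Housekeeping gene id (required for file input; synthetic
#'   datasets carry their own).
#' @param stages Character vector of stages to run, a subset (in order) of
#'   `c("normalize", "model", "estimate", "de", "activity", "clusters",
#'   "enrichment")`. Later stages require their prerequisites.
#' @param alpha,abundance_floor,fc_floor DE thresholds.
#' @param trim_alpha Outlier-trim threshold of [estimate_mean_trimmed()].
#' @param min_bin_size,min_mean Dispersion-binning controls.
#' @param n_permutations Permutations for the activity shift tests.
#' @param min_set_size Gene-set eligibility threshold.
#' @param association_fold Fold threshold of [timepoint_association()].
#' @param seed Master seed for all stochastic stages.
#' @param outdir Output directory for TSV tables and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = simulation_config(),
                            counts_path = NULL, hk_gene = NULL,
                            stages = c("normalize", "model", "estimate",
                                       "de", "activity", "clusters",
                                       "enrichment"),
                            alpha = 0.05, abundance_floor = 8,
                            fc_floor = 0.9, trim_alpha = 0.05,
                            min_bin_size = 30, min_mean = 8,
                            n_permutations = 10000, min_set_size = 100,
                            association_fold = 2, seed = 1L,
                            outdir = tempfile("countshift_run_")) {
  structure(list(synthetic = synthetic, counts_path = counts_path,
                 hk_gene = hk_gene, stages = stages, alpha = alpha,
                 abundance_floor = abundance_floor, fc_floor = fc_floor,
                 trim_alpha = trim_alpha, min_bin_size = min_bin_size,
                 min_mean = min_mean, n_permutations = n_permutations,
                 min_set_size = min_set_size,
                 association_fold = association_fold,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

estimates_to_matrix <- function(estimates, line, timepoints) {
  est <- estimates[estimates$line == line & !estimates$excluded, ]
  genes <- sort(unique(est$gene))
  m <- matrix(NA_real_, length(genes), length(timepoints),
              dimnames = list(genes, timepoints))
  for (tp in timepoints) {
    sub <- est[est$timepoint == tp, ]
    m[sub$gene, tp] <- sub$mean
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic generation (or count-matrix ingestion),
#' housekeeping normalization with the size-factor check, dispersion-trend
#' modeling, outlier-trimmed mean estimation, Wald differential expression,
#' transcriptome-activity shifts (per-timepoint between-line shifts plus
#' diurnal variance), timepoint-association clustering in both lines, and
#' BP/pathway enrichment of the DEG sets. Every stage writes its table
#' under `config$outdir`; a `manifest.json` records stages, parameters and
#' funnel counts. Identical configs and seeds give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with the per-stage objects and a
#'   `report` list (DEG counts per timepoint and chromosome, UP/DOWN
#'   ratios, between-line shifts, cluster preservation, MAD activity
#'   curves).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages_done = character(0),
                   params = config[setdiff(names(config),
                                           c("synthetic", "outdir"))],
                   log = list())
  res <- list(config = config)
  say <- function(stage, ...) {
    manifest$log[[stage]] <<- paste0(...)
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- config$seed
    res$dataset <- generate_dataset(cfg)
    cm <- res$dataset$counts
    hk <- res$dataset$housekeeping_gene
    annotations <- res$dataset$annotations
  } else {
    if (is.null(config$counts_path)) stop("no input: synthetic config and counts_path both NULL")
    cm <- read_count_matrix(config$counts_path, hk_gene = config$hk_gene)
    hk <- config$hk_gene
    annotations <- NULL
  }
  timepoints <- unique(cm$samples$timepoint)
  lines <- unique(cm$samples$line)
  manifest$stages_done <- c(manifest$stages_done, "input")

  run <- function(stage) stage %in% config$stages

  # --- normalize -----------------------------------------------------------
  if (run("normalize")) {
    cm <- normalize_to_housekeeping(cm, hk)
    res$size_factors <- size_factors(cm)
    say("normalize", "size factors: mean ",
        signif(mean(res$size_factors), 4), ", median ",
        signif(stats::median(res$size_factors), 4))
    write_count_matrix(cm, file.path(config$outdir, "counts_normalized.tsv"))
    manifest$stages_done <- c(manifest$stages_done, "normalize")
  }
  res$counts <- cm

  # --- model ---------------------------------------------------------------
  if (run("model")) {
    cells <- list()
    groups <- unique(cm$samples[, c("line", "timepoint")])
    for (g in seq_len(nrow(groups))) {
      cols <- cm$samples$line == groups$line[g] &
        cm$samples$timepoint == groups$timepoint[g]
      cells <- c(cells, asplit(cm$values[, cols, drop = FALSE], 1L))
    }
    bins <- pool_bins(cells, min_mean = config$min_mean,
                      min_bin_size = config$min_bin_size)
    res$trend <- fit_theta_trend(bins)
    say("model", length(bins), " bins from ",
        sum(vapply(bins, function(b) b$n, numeric(1))), " cells")
    write_theta_trend(res$trend, file.path(config$outdir, "theta_trend.json"))
    manifest$stages_done <- c(manifest$stages_done, "model")
  }

  # --- estimate ------------------------------------------------------------
  if (run("estimate")) {
    res$estimates <- estimate_means(cm, res$trend, alpha = config$trim_alpha)
    say("estimate", sum(res$estimates$excluded), " of ",
        nrow(res$estimates), " cells excluded; ",
        sum(res$estimates$n_outliers), " outliers trimmed")
    utils::write.table(res$estimates,
                       file.path(config$outdir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages_done <- c(manifest$stages_done, "estimate")
  }

  # --- de ------------------------------------------------------------------
  if (run("de")) {
    res$de <- de_table(res$estimates, res$trend,
                       abundance_floor = config$abundance_floor,
                       fc_floor = config$fc_floor, alpha = config$alpha)
    say("de", sum(res$de$status != "NONE"), " DEG calls from ",
        nrow(res$de), " tests")
    utils::write.table(res$de, file.path(config$outdir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages_done <- c(manifest$stages_done, "de")
  }

  # --- activity ------------------------------------------------------------
  if (run("activity")) {
    expr <- lapply(stats::setNames(lines, lines), function(l) {
      estimates_to_matrix(res$estimates, l, timepoints)
    })
    common <- Reduce(intersect, lapply(expr, rownames))
    expressed <- common[Reduce(`|`, lapply(expr, function(m) {
      rowSums(m[common, , drop = FALSE] >= config$abundance_floor) > 0
    }))]
    res$activity <- lapply(stats::setNames(timepoints, timepoints),
                           function(tp) {
      permutation_test(expr[[1]][expressed, tp], expr[[2]][expressed, tp],
                       sidedness = "two",
                       n_permutations = config$n_permutations,
                       seed = config$seed + match(tp, timepoints))
    })
    res$diurnal_variance <- lapply(expr, function(m) {
      diurnal_variance(m[expressed, , drop = FALSE],
                       floor = config$abundance_floor)
    })
    act <- data.frame(
      timepoint = timepoints,
      shift = vapply(res$activity, `[[`, numeric(1), "shift"),
      p_exact = vapply(res$activity, `[[`, numeric(1), "p_exact"))
    utils::write.table(act, file.path(config$outdir, "activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("activity", length(expressed), " expressed genes tested")
    manifest$stages_done <- c(manifest$stages_done, "activity")
  }

  # --- clusters ------------------------------------------------------------
  if (run("clusters")) {
    res$clusters <- lapply(stats::setNames(lines, lines), function(l) {
      timepoint_association(res$estimates[res$estimates$line == l, ],
                            res$trend, fold = config$association_fold,
                            alpha = config$alpha,
                            floor = config$abundance_floor)
    })
    for (l in lines) {
      utils::write.table(res$clusters[[l]],
                         file.path(config$outdir,
                                   paste0("clusters_", l, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages_done <- c(manifest$stages_done, "clusters")
  }

  # --- enrichment ----------------------------------------------------------
  if (run("enrichment") && !is.null(annotations)) {
    universe <- unique(res$estimates$gene[
      res$estimates$mean >= config$abundance_floor &
        !res$estimates$excluded])
    hit_sets <- list()
    for (tp in timepoints) {
      for (st in c("UP", "DOWN")) {
        hits <- res$de$gene[res$de$timepoint == tp & res$de$status == st]
        if (length(hits) > 0) hit_sets[[paste(tp, st, sep = "_")]] <- hits
      }
    }
    res$enrichment <- enrich_all(
      hit_sets,
      list(BP = annotations$bp, pathway = annotations$pathway),
      universe = universe, alpha = config$alpha)
    utils::write.table(res$enrichment,
                       file.path(config$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("enrichment", nrow(res$enrichment), " significant terms")
    manifest$stages_done <- c(manifest$stages_done, "enrichment")
  }

  # --- report --------------------------------------------------------------
  report <- list()
  if (!is.null(res$de)) {
    report$updown_ratio <- vapply(
      stats::setNames(timepoints, timepoints),
      function(tp) report_updown_ratio(res$de, tp), numeric(1))
    report$deg_per_timepoint <- vapply(
      stats::setNames(timepoints, timepoints),
      function(tp) sum(res$de$timepoint == tp & res$de$status != "NONE"),
      numeric(1))
    if (!is.null(annotations)) {
      degs <- unique(res$de$gene[res$de$status != "NONE"])
      report$deg_per_chromosome <-
        table(annotations$chromosome[degs])
    }
  }
  if (!is.null(res$activity)) {
    report$shift <- vapply(res$activity, `[[`, numeric(1), "shift")
  }
  if (!is.null(res$clusters) && length(res$clusters) >= 2) {
    report$cluster_preservation <-
      report_cluster_preservation(res$clusters[[1]], res$clusters[[2]])
  }
  if (!is.null(res$estimates)) {
    report$activity_curves <- report_activity_curves(res$estimates)
  }
  res$report <- report
  manifest$report <- list(
    updown_ratio = report$updown_ratio,
    deg_per_timepoint = report$deg_per_timepoint,
    shift = report$shift)
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: stages", paste(x$manifest$stages_done, collapse = " -> "),
      "\n  outdir:", x$config$outdir, "\n")
  invisible(x)
}

#' UP/DOWN ratio of DEG calls at a timepoint
#'
#' @param de A DE table (see [call_degs()]).
#' @param timepoint Timepoint label.
#' @return `count(UP) / count(DOWN)`; `Inf` when DOWN is 0 and UP positive,
#'   `NA` when both are 0.
#' @export
report_updown_ratio <- function(de, timepoint) {
  sub <- de[de$timepoint == timepoint, ]
  up <- sum(sub$status == "UP")
  down <- sum(sub$status == "DOWN")
  if (up == 0 && down == 0) return(NA_real_)
  up / down
}

#' Preservation of timepoint clusters between lines
#'
#' Per (timepoint, direction): the fraction of the reference line's cluster
#' members also clustered the same way in the other line, plus the flow of
#' non-preserved genes into the opposite-direction cluster at any timepoint.
#'
#' @param clusters_a,clusters_b Cluster tables of the two lines
#'   ([timepoint_association()] output).
#' @return List: `rates` (data frame `timepoint`, `direction`, `n_a`,
#'   `n_preserved`, `rate`), `opposite_flow` (data frame of non-preserved
#'   reference genes found in an opposite-direction cluster of the other
#'   line, with the fraction per source cluster).
#' @export
report_cluster_preservation <- function(clusters_a, clusters_b) {
  keys <- unique(clusters_a[, c("timepoint", "direction")])
  flip <- c(overexpressed = "underexpressed",
            underexpressed = "overexpressed")
  rates <- list()
  flows <- list()
  for (i in seq_len(nrow(keys))) {
    tp <- keys$timepoint[i]
    dir <- keys$direction[i]
    ga <- clusters_a$gene[clusters_a$timepoint == tp &
                            clusters_a$direction == dir]
    gb <- clusters_b$gene[clusters_b$timepoint == tp &
                            clusters_b$direction == dir]
    preserved <- intersect(ga, gb)
    rates[[i]] <- data.frame(timepoint = tp, direction = dir,
                             n_a = length(ga),
                             n_preserved = length(preserved),
                             rate = length(preserved) / length(ga))
    lost <- setdiff(ga, gb)
    opp <- clusters_b$gene[clusters_b$direction == flip[dir]]
    flows[[i]] <- data.frame(timepoint = tp, direction = dir,
                             n_lost = length(lost),
                             n_opposite = length(intersect(lost, opp)),
                             fraction_opposite =
                               if (length(ga)) length(intersect(lost, opp)) /
                                 length(ga) else NA_real_)
  }
  list(rates = do.call(rbind, rates), opposite_flow = do.call(rbind, flows))
}

#' Per-sample MAD activity curves
#'
#' Median absolute deviation (unscaled: `median(|x - median(x)|)`) of the
#' estimated mean counts across genes, per (line, timepoint) — the
#' plotting-ready summary of diurnal transcriptome activity.
#'
#' @param estimates Output of [estimate_means()].
#' @return Data frame `line`, `timepoint`, `mad`, `n_genes`.
#' @export
report_activity_curves <- function(estimates) {
  est <- estimates[!estimates$excluded, ]
  keys <- unique(est[, c("line", "timepoint")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    x <- est$mean[est$line == keys$line[i] &
                    est$timepoint == keys$timepoint[i]]
    data.frame(line = keys$line[i], timepoint = keys$timepoint[i],
               mad = stats::median(abs(x - stats::median(x))),
               n_genes = length(x))
  })
  do.call(rbind, out)
}
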