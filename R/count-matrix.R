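#' Count matrix with sample metadata
#'
#' Container for a genes-by-samples matrix of (possibly normalized) counts
#' together with the sample metadata of the assumed design: genotype line,
#' photoperiod timepoint and replicate index.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param samples Data frame with one row per column of `values` and columns
#'   `line`, `timepoint`, `replicate`. Row order must match column order.
#' @param hk_gene Optional housekeeping gene id (a rowname of `values`).
#' @param norm_factors Per-sample normalization factors already applied
#'   (default 1).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, samples, hk_gene = NULL,
                         norm_factors = rep(1, ncol(values))) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            nrow(samples) == ncol(values),
            all(c("line", "timepoint", "replicate") %in% names(samples)))
  if (any(values < 0)) stop("counts must be nonnegative")
  if (!is.null(hk_gene) && !hk_gene %in% rownames(values)) {
    stop("housekeeping gene ", hk_gene, " is not a row of the matrix")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_%s_rep%d", samples$line,
                                samples$timepoint, samples$replicate)
  }
  structure(list(values = values, samples = samples, hk_gene = hk_gene,
                 norm_factors = norm_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s; timepoints %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$line), collapse = "/"),
              paste(unique(x$samples$timepoint), collapse = ", ")))
  if (!is.null(x$hk_gene)) cat("  housekeeping gene:", x$hk_gene, "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Normalize a count matrix to a housekeeping gene
#'
#' Scales every sample by `reference / hk_count`, where the reference level
#' is the geometric mean of the housekeeping gene's counts across samples
#' (which makes the operation symmetric in the samples and idempotent).
#' After normalization the housekeeping gene is constant across samples.
#'
#' @param cm A [count_matrix()].
#' @param hk_gene Housekeeping gene id; defaults to `cm$hk_gene`.
#' @return A normalized `count_matrix` (norm factors recorded).
#' @export
normalize_to_housekeeping <- function(cm, hk_gene = cm$hk_gene) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(hk_gene)) stop("no housekeeping gene specified")
  hk <- cm$values[hk_gene, ]
  if (any(hk <= 0)) {
    bad <- colnames(cm$values)[hk <= 0]
    stop("housekeeping gene ", hk_gene, " has zero count in sample(s): ",
         paste(bad, collapse = ", "))
  }
  ref <- exp(mean(log(hk)))
  f <- ref / hk
  out <- cm
  out$values <- sweep(cm$values, 2L, f, `*`)
  out$hk_gene <- hk_gene
  out$norm_factors <- cm$norm_factors * f
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style size factors: each sample's median ratio to the per-gene
#' geometric-mean reference, computed over genes with nonzero counts in
#' every sample. Under the assumption that most genes are not differentially
#' expressed, well-normalized libraries have factors close to 1.
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$values
  if (ncol(v) < 2L) stop("at least 2 samples are required")
  pos <- rowSums(v <= 0) == 0L
  if (!any(pos)) stop("no gene has a nonzero count in every sample")
  lv <- log(v[pos, , drop = FALSE])
  ref <- rowMeans(lv)
  apply(lv, 2L, function(col) exp(stats::median(col - ref)))
}

#' Read / write a count matrix as TSV
#'
#' The TSV layout is one `gene` column plus one column per sample named
#' `<line>_<timepoint>_rep<k>`; metadata is recovered from the column names.
#'
#' @param cm A [count_matrix()].
#' @param path File path.
#' @param hk_gene Housekeeping gene id to attach on read.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$values), cm$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, hk_gene = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  meta <- do.call(rbind, lapply(strsplit(colnames(values), "_"), function(p) {
    data.frame(line = p[1], timepoint = p[2],
               replicate = as.integer(sub("^rep", "", p[3])))
  }))
  count_matrix(values, meta, hk_gene = hk_gene)
}
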