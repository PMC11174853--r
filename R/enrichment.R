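# Fisher's exact over/under-representation with paralog adjustment.

#' Fisher's exact test of over- or under-representation
#'
#' Exact hypergeometric tail probability of the 2x2 table (hits in term,
#' hits outside term, term outside hits, rest) against the gene universe.
#' The `greater` tail tests over-representation; the `less` tail serves
#' under-representation calls.
#'
#' @param hits Character vector of hit gene ids (must lie in `universe`).
#' @param term_genes Gene ids of the annotation term.
#' @param universe All quantifiable gene ids (the background).
#' @param tail `"greater"` (default) or `"less"`.
#' @return List: `odds_ratio` (sample cross-product ratio), `p`, `table`
#'   (the 2x2 matrix), `overlap`, `expected`.
#' @export
fisher_overrep <- function(hits, term_genes, universe,
                           tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  term_genes <- intersect(unique(term_genes), universe)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  k <- length(intersect(hits, term_genes))
  tab <- matrix(c(k,
                  length(hits) - k,
                  length(term_genes) - k,
                  length(universe) - length(hits) - length(term_genes) + k),
                nrow = 2,
                dimnames = list(c("term", "notterm"), c("hit", "nothit")))
  p <- stats::fisher.test(tab, alternative = tail)$p.value
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  expected <- length(hits) * length(term_genes) / length(universe)
  list(odds_ratio = odds, p = p, table = tab, overlap = k,
       expected = expected)
}

#' Over-representation analysis across hit sets and annotation classes
#'
#' Tests every term of every annotation class against every hit set,
#' BH-adjusts the p-values within each (hit set, term class) family, and
#' drops rows with adjusted p at or above `alpha`.
#'
#' @param hit_sets Named list of hit gene-id vectors (e.g. one per
#'   timepoint/direction).
#' @param annotations Data frame with columns `gene`, `term`, `class`
#'   (class e.g. `"BP"`, `"pathway"`), or a named list of such frames
#'   (names become classes).
#' @param universe Background gene ids.
#' @param alpha Adjusted-p cutoff for the returned table (default 0.05).
#' @param tail Passed to [fisher_overrep()].
#' @return Data frame `hit_set`, `class`, `term`, `hits`, `expected`,
#'   `odds_ratio`, `p`, `p_adj`, filtered to `p_adj < alpha`.
#' @export
enrich_all <- function(hit_sets, annotations, universe, alpha = 0.05,
                       tail = "greater") {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "term", "class") %in% names(annotations)))
  } else {
    annotations <- do.call(rbind, lapply(names(annotations), function(cl) {
      cbind(annotations[[cl]][, c("gene", "term")], class = cl)
    }))
  }
  annotations <- annotations[annotations$gene %in% universe, , drop = FALSE]
  rows <- list()
  for (hs in names(hit_sets)) {
    hits <- intersect(hit_sets[[hs]], universe)
    if (length(hits) == 0L) next
    for (cl in unique(annotations$class)) {
      sub <- annotations[annotations$class == cl, ]
      terms <- unique(sub$term)
      fam <- lapply(terms, function(tm) {
        fisher_overrep(hits, sub$gene[sub$term == tm], universe, tail = tail)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        hit_set = hs, class = cl, term = terms,
        hits = vapply(fam, `[[`, numeric(1), "overlap"),
        expected = vapply(fam, `[[`, numeric(1), "expected"),
        odds_ratio = vapply(fam, `[[`, numeric(1), "odds_ratio"),
        p = vapply(fam, `[[`, numeric(1), "p"),
        p_adj = bh_adjust(vapply(fam, `[[`, numeric(1), "p")))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(hit_set = character(0), class = character(0),
                      term = character(0), hits = numeric(0),
                      expected = numeric(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[!is.na(out$p_adj) & out$p_adj < alpha, , drop = FALSE]
}

#' Paralog content of a gene set, with the paralog-adjusted comparison
#'
#' Computes the mean number of paralog partners per gene of the set (a gene
#' in a cluster of size `s` has `s - 1` partners; unclustered genes have 0),
#' both over all set genes and restricted to genes with at least one
#' paralog — the restriction the adjusted enrichment comparison uses. The
#' accompanying Fisher test compares the proportion of paralog-bearing
#' genes in the set against the (restrictable) universe.
#'
#' @param set Gene ids of the tested set.
#' @param clusters Named character vector gene -> paralog cluster id
#'   (`NA` = no cluster).
#' @param universe Background gene ids (default: all genes in `clusters`).
#' @return List: `paralogs_per_gene`, `paralogs_per_gene_adjusted` (NaN for
#'   a set with no paralog-bearing gene), `n_with_paralog`, `test`
#'   (a [fisher_overrep()] result over the paralog-bearing universe, or
#'   `NULL` when degenerate).
#' @export
paralog_enrichment <- function(set, clusters, universe = names(clusters)) {
  stopifnot(!is.null(names(clusters)))
  cl_sizes <- table(clusters[!is.na(clusters)])
  partners <- function(genes) {
    cl <- clusters[genes]
    ifelse(is.na(cl), 0, as.integer(cl_sizes[cl]) - 1L)
  }
  pset <- partners(set)
  with_par <- set[pset > 0]
  universe_par <- universe[partners(universe) > 0]
  test <- if (length(universe_par) > 0 && length(with_par) > 0) {
    fisher_overrep(intersect(set, universe), universe_par, universe,
                   tail = "greater")
  } else NULL
  list(paralogs_per_gene = mean(pset),
       paralogs_per_gene_adjusted = mean(pset[pset > 0]),
       n_with_paralog = length(with_par),
       test = test)
}

#' Read a 2-column annotation map TSV
#'
#' @param path TSV with columns `gene` and a term/value column.
#' @return Data frame as read (first column `gene`).
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, colClasses = "character")
}
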