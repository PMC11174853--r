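# Read QC and greatest-depth transcript quantification.
#
# Transcript abundance is taken as the greatest depth of coverage over the
# transcript: assuming fragments of one transcript copy do not overlap, the
# maximum number of simultaneously overlapping fragments equals the number of
# transcript copies, independently of transcript length. Only uniquely and
# completely mapped reads enter the depth computation.

#' Quality-trim a read
#'
#' Trims bases from each end until the terminal `end_span` bases on both
#' sides all exceed `quality_floor`; reads shorter than `min_length` after
#' trimming are discarded. Discarding is a normal outcome, signalled by
#' `NULL`.
#'
#' @param qualities Integer vector of per-base qualities (5' to 3').
#' @param quality_floor Qualities must be strictly greater than this
#'   (default 3).
#' @param end_span Number of terminal bases on each side that must pass
#'   (default 10).
#' @param min_length Minimum retained length (default 30).
#' @return `NULL` if the read is discarded, otherwise a list with `from`,
#'   `to` (1-based kept range) and `length`.
#' @export
qc_trim <- function(qualities, quality_floor = 3, end_span = 10,
                    min_length = 30) {
  n <- length(qualities)
  if (n < min_length) return(NULL)
  ok <- qualities > quality_floor
  # smallest start such that the next end_span bases all pass
  runs <- which(stats::filter(as.numeric(ok), rep(1, end_span),
                              sides = 1) == end_span)
  if (length(runs) == 0L) return(NULL)
  from <- min(runs) - end_span + 1L
  to <- max(runs)
  len <- to - from + 1L
  if (len < min_length) return(NULL)
  list(from = from, to = to, length = len)
}

#' Greatest depth of coverage of a set of intervals
#'
#' Returns the maximum, over transcript positions, of the number of covering
#' intervals. Coordinates are 0-based half-open (`start <= pos < end`). Only
#' intervals from reads passing the unique and complete filters should be
#' passed in.
#'
#' @param starts,ends Integer vectors of interval starts and ends
#'   (`start < end`), or a 2-column matrix/data.frame given as `starts`.
#' @return Nonnegative integer: the greatest coverage depth (0 for no
#'   intervals).
#' @export
max_depth_count <- function(starts, ends = NULL) {
  if (is.null(ends)) {
    if (length(starts) == 0L) return(0L)
    m <- as.matrix(starts)
    starts <- m[, 1]
    ends <- m[, 2]
  }
  if (length(starts) == 0L) return(0L)
  stopifnot(length(starts) == length(ends), all(starts < ends))
  pos <- c(starts, ends)
  delta <- c(rep(1L, length(starts)), rep(-1L, length(ends)))
  # half-open: an interval ending at p does not cover p, so ends sort first
  ord <- order(pos, delta)
  max(cummax(cumsum(delta[ord])))
}

#' Quantify genes from an alignment-interval table
#'
#' Filters alignment intervals to uniquely and completely mapped records and
#' computes the greatest coverage depth per (transcript, sample).
#'
#' @param alignments Data frame with columns `transcript`, `sample`, `start`,
#'   `end`, `unique`, `complete` (as written by [make_read_alignments()] or
#'   [read_alignments()]).
#' @param genes Gene ids to report (genes without surviving intervals get
#'   count 0). Default: transcripts present in the table.
#' @param samples Sample names to report; default those present.
#' @return Integer matrix genes x samples of greatest-depth counts.
#' @export
quantify_alignments <- function(alignments, genes = NULL, samples = NULL) {
  req <- c("transcript", "sample", "start", "end", "unique", "complete")
  stopifnot(all(req %in% names(alignments)))
  if (is.null(genes)) genes <- sort(unique(alignments$transcript))
  if (is.null(samples)) samples <- sort(unique(alignments$sample))
  keep <- alignments$unique & alignments$complete
  al <- alignments[keep, , drop = FALSE]
  out <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(al) > 0L) {
    key <- split(seq_len(nrow(al)), list(factor(al$transcript, genes),
                                         factor(al$sample, samples)),
                 drop = TRUE)
    for (k in names(key)) {
      idx <- key[[k]]
      g <- al$transcript[idx[1]]
      s <- al$sample[idx[1]]
      out[g, s] <- max_depth_count(al$start[idx], al$end[idx])
    }
  }
  out
}

#' Read / write alignment-interval tables as TSV
#'
#' @param alignments Alignment data frame (see [quantify_alignments()]).
#' @param path File path.
#' @return `write_alignments` returns `path` invisibly; `read_alignments`
#'   returns the data frame with logical `unique`/`complete` columns.
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  df <- utils::read.delim(path)
  df$unique <- as.logical(df$unique)
  df$complete <- as.logical(df$complete)
  df
}
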