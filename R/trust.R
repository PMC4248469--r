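#' Pass 1: subsample read k-mers into a Bloom filter
#'
#' Every valid k-mer window of every read independently survives with
#' probability `alpha`; survivors are canonicalized and added to `filter`.
#' The Bernoulli draw for a window is a pure function of `(seed, read
#' ordinal, window offset)`, so the sample does not depend on read order or
#' on how the stream is chunked (`read_offset` carries the ordinal of the
#' first read in a chunk). Windows containing `N` (or any ambiguity code)
#' are never sampled. A distinct k-mer occurring `N_a` times is absent from
#' the filter with probability `(1 - alpha)^N_a`.
#'
#' @param reads A tibble with at least a `seq` column (see [read_fastx()]).
#' @param k k-mer length (1–31).
#' @param alpha Subsampling fraction in `(0, 1]`.
#' @param filter A [bloom_filter()] (or [kmer_hashset()]) receiving
#'   survivors; modified in place.
#' @param seed Integer seed for the subsampling stream.
#' @param read_offset Ordinal of the first read of `reads` within the whole
#'   dataset (0 for a single in-memory batch).
#' @return One-row tibble: `windows_total`, `windows_valid`, `survivors`,
#'   `inserts`, and for Bloom filters `occupancy` and `est_fp`.
#' @export
sample_kmers <- function(reads, k, alpha, filter, seed = 1L, read_offset = 0) {
  stopifnot(is.data.frame(reads), "seq" %in% names(reads),
            k >= 1, k <= 31, inherits(filter, "kmer_set"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  res <- .sample_kmers_cpp(reads$seq, as.integer(k), alpha, as.numeric(seed),
                           as.numeric(read_offset), filter$ptr)
  out <- tibble::tibble(
    windows_total = res$windows_total,
    windows_valid = res$windows_valid,
    survivors = res$survivors,
    inserts = .set_n_add_cpp(filter$ptr)
  )
  if (inherits(filter, "bloom_filter")) {
    s <- bloom_stats(filter)
    out$occupancy <- s$occupancy
    out$est_fp <- s$est_fp
  }
  out
}

#' Quality-score cutoff from the read stream
#'
#' Scans (up to) the first `max_reads` reads and takes the fifth-percentile
#' quality at the last read position (`t1`) and at the first position
#' (`t2`); the percentile is the smallest value with at least
#' `ceiling(0.05 * n)` values less than or equal to it. The trust cutoff is
#' `min(t1, t2 - 1)` on the integer Phred scale: any position with quality
#' at or below the cutoff is untrusted regardless of its k-mer support.
#'
#' Reads without quality strings (FASTA input) disable the gate: the cutoff
#' becomes `-Inf` and no position is flagged low-quality.
#'
#' @param reads Tibble with a `qual` column of Phred strings (may be `NA`).
#' @param max_reads Maximum reads examined (default 1e6).
#' @param phred_offset ASCII offset of the encoding (default 33).
#' @return An object of class `quality_thresholds`: list with `t1`, `t2`,
#'   `cutoff`, `sample_size`, `phred_offset`.
#' @export
quality_thresholds <- function(reads, max_reads = 1e6, phred_offset = 33L) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) stop("empty read stream")
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  qual <- qual[!is.na(qual)]
  if (length(qual) == 0) {
    out <- list(t1 = NA_integer_, t2 = NA_integer_, cutoff = -Inf,
                sample_size = 0L, phred_offset = as.integer(phred_offset))
    class(out) <- "quality_thresholds"
    return(out)
  }
  qual <- qual[seq_len(min(length(qual), max_reads))]
  first <- utf8ToInt(paste(substr(qual, 1, 1), collapse = "")) - phred_offset
  n <- nchar(qual)
  last <- utf8ToInt(paste(substr(qual, n, n), collapse = "")) - phred_offset
  pct5 <- function(v) sort(v)[ceiling(0.05 * length(v))]
  t1 <- pct5(last)
  t2 <- pct5(first)
  out <- list(t1 = t1, t2 = t2, cutoff = min(t1, t2 - 1),
              sample_size = length(qual),
              phred_offset = as.integer(phred_offset))
  class(out) <- "quality_thresholds"
  out
}

#' @export
print.quality_thresholds <- function(x, ...) {
  if (!is.finite(x$cutoff)) {
    cat("<quality_thresholds> disabled (no quality data)\n")
  } else {
    cat(sprintf(
      "<quality_thresholds> t1=%d t2=%d cutoff=%d (Phred, %d reads sampled)\n",
      x$t1, x$t2, x$cutoff, x$sample_size
    ))
  }
  invisible(x)
}

.cutoff_int <- function(qthresh) {
  if (is.null(qthresh) || !is.finite(qthresh$cutoff)) -1000000000L
  else as.integer(qthresh$cutoff)
}

#' Pass 2 trust test for one read
#'
#' For each position `i` of the read: `x` counts the k-mer windows that
#' overlap it (invalid, `N`-containing windows included), `hits` counts how
#' many of those windows are found (canonically) in the subsample filter
#' (invalid windows can never hit), and the position is `trusted` when
#' `hits >= y[x]` and its quality exceeds the cutoff. Positions of reads
#' shorter than `k` are all untrusted (`x = 0`).
#'
#' @param seq Read sequence (single string).
#' @param filterA The pass-1 subsample filter.
#' @param thresholds A [trust_thresholds()] table for the same `k`.
#' @param qthresh A [quality_thresholds()] object, or `NULL` to disable the
#'   quality gate.
#' @param qual Phred string of the read, or `NULL`.
#' @return Tibble with columns `position`, `x`, `hits`, `trusted`.
#' @export
trust_positions <- function(seq, filterA, thresholds, qthresh = NULL,
                            qual = NULL) {
  stopifnot(is.character(seq), length(seq) == 1,
            inherits(filterA, "kmer_set"), is.data.frame(thresholds))
  k <- nrow(thresholds)
  off <- if (is.null(qthresh)) 33L else qthresh$phred_offset
  r <- .trust_read_cpp(seq, qual, as.integer(k), filterA$ptr,
                       as.integer(thresholds$y), .cutoff_int(qthresh),
                       as.integer(off))
  tibble::tibble(position = seq_len(nchar(seq)), x = r$x, hits = r$hits,
                 trusted = r$trusted)
}

#' Collect solid k-mers of one read
#'
#' Every valid window whose `k` positions are all trusted is canonicalized
#' and added to `filterB` (check-then-insert, so repeated solid k-mers do
#' not inflate the filter's insert count).
#'
#' @inheritParams trust_positions
#' @param trusted Logical per-position trust vector (from
#'   [trust_positions()]).
#' @param k k-mer length.
#' @param filterB Destination filter for solid k-mers; modified in place.
#' @return Number of k-mers newly added.
#' @export
collect_solid <- function(seq, trusted, k, filterB) {
  stopifnot(is.character(seq), length(seq) == 1, is.logical(trusted),
            inherits(filterB, "kmer_set"))
  .collect_solid_cpp(seq, trusted, as.integer(k), filterB$ptr)
}

#' Pass 2 over a whole read set
#'
#' Applies the per-position trust test to every read and adds all solid
#' k-mers to `filterB`. The result depends only on the reads, the contents
#' of `filterA` and the thresholds — not on read order.
#'
#' @inheritParams trust_positions
#' @param reads Read tibble (`seq`, optionally `qual`).
#' @param filterB Destination filter for solid k-mers; modified in place.
#' @return One-row tibble: `solid_added`, `trusted_positions`, `positions`.
#' @export
build_solid_filter <- function(reads, filterA, thresholds, qthresh, filterB) {
  stopifnot(is.data.frame(reads), inherits(filterA, "kmer_set"),
            inherits(filterB, "kmer_set"), is.data.frame(thresholds))
  k <- nrow(thresholds)
  quals <- if ("qual" %in% names(reads)) reads$qual else NULL
  off <- if (is.null(qthresh)) 33L else qthresh$phred_offset
  r <- .pass2_cpp(reads$seq, quals, as.integer(k), filterA$ptr,
                  as.integer(thresholds$y), .cutoff_int(qthresh),
                  as.integer(off), filterB$ptr)
  tibble::tibble(solid_added = r$solid_added,
                 trusted_positions = r$trusted_positions,
                 positions = r$positions)
}
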