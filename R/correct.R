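#' Anchor: longest run of solid k-mers in a read
#'
#' Finds the leftmost maximal-length run of consecutive windows all present
#' (canonically) in the solid filter. Correction extends rightward from the
#' run's right end and leftward from its left end.
#'
#' @param seq Read sequence.
#' @param filterB Solid k-mer filter.
#' @param k k-mer length.
#' @return Integer vector `c(start, end)` of 1-based window offsets, or an
#'   empty vector when no window is in the filter (the read cannot be
#'   corrected).
#' @export
find_anchor <- function(seq, filterB, k) {
  stopifnot(is.character(seq), length(seq) == 1, inherits(filterB, "kmer_set"))
  .find_anchor_cpp(seq, as.integer(k), filterB$ptr)
}

#' Score a candidate substitution
#'
#' With `base` substituted at `pos`, counts how many consecutive windows
#' starting at the failing window (the window whose extreme position is
#' `pos`, moving in `direction`) appear in the solid filter, up to `k`. When
#' the count reaches the read end unbroken, it continues virtually beyond
#' the end: each extra step counts only if exactly one nucleotide extends
#' the current `k-1` suffix to a k-mer in the filter. The leftward direction
#' is evaluated on the reverse complement (the filter is strand-symmetric
#' under canonicalization).
#'
#' @param seq Read sequence.
#' @param pos 1-based position of the presumed error.
#' @param base Candidate base (`A`, `C`, `G` or `T`).
#' @param filterB Solid k-mer filter.
#' @param k k-mer length.
#' @param direction `"right"` (default) or `"left"`.
#' @return Integer stretch length in `[0, k]`.
#' @export
score_substitution <- function(seq, pos, base, filterB, k,
                               direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(is.character(seq), length(seq) == 1, inherits(filterB, "kmer_set"))
  .score_substitution_cpp(seq, as.integer(pos) - 1L, base, as.integer(k),
                          filterB$ptr, direction == "left")
}

#' Greedy substitution correction of one read
#'
#' Implements the third pass for a single read: anchor on the longest run
#' of solid windows, then walk rightward (and mirrored leftward through the
#' reverse complement). At the first window absent from the filter, the
#' window's extreme position is presumed erroneous; all four bases are
#' scored with [score_substitution()] and the unique maximizer (if its
#' stretch is at least 1) is applied. Ties leave the position uncorrected
#' and flagged ambiguous, with scanning resuming `k` windows later.
#'
#' A weighted budget caps edits: within any window of `k` consecutive
#' positions the applied edit weights may total at most `limit`, where an
#' edit at an original `N` weighs 0, at a low-quality base (quality at or
#' below the [quality_thresholds()] cutoff) 0.5, and 1 otherwise. An edit
#' that would exceed the budget is not applied and ends extension in that
#' direction.
#'
#' Reads shorter than `k`, or with no window in the filter, are returned
#' unchanged with `anchored = FALSE`. Corrections never change read length,
#' and qualities are left untouched.
#'
#' @param seq Read sequence.
#' @param filterB Solid k-mer filter.
#' @param k k-mer length.
#' @param qual Phred string or `NULL`.
#' @param qthresh A [quality_thresholds()] object or `NULL`.
#' @param limit Correction budget per k-window (default 4).
#' @return A list of class `read_correction`: `seq` (corrected), `edits`
#'   (tibble `pos`, `from`, `to`, `weight`), `ambiguous` (positions),
#'   `budget_stop`, `anchored`.
#' @examples
#' B <- kmer_hashset("ACGTTGCAATGCCGTA", k = 5)
#' correct_read("ACGTTGCAATGACGTA", B, k = 5)$edits
#' @export
correct_read <- function(seq, filterB, k, qual = NULL, qthresh = NULL,
                         limit = 4) {
  stopifnot(is.character(seq), length(seq) == 1, inherits(filterB, "kmer_set"),
            k >= 1, k <= 31, limit >= 0)
  off <- if (is.null(qthresh)) 33L else qthresh$phred_offset
  r <- .correct_read_cpp(seq, qual, as.integer(k), filterB$ptr,
                         .cutoff_int(qthresh), as.integer(off), limit)
  out <- list(
    seq = r$seq,
    edits = tibble::tibble(pos = r$pos, from = as.character(r$from),
                           to = as.character(r$to), weight = r$weight),
    ambiguous = r$ambiguous,
    budget_stop = r$budget_stop,
    anchored = r$anchored
  )
  class(out) <- "read_correction"
  out
}

#' @export
print.read_correction <- function(x, ...) {
  cat(sprintf("<read_correction> %d edit(s), %d ambiguous, %sanchored%s\n",
              nrow(x$edits), length(x$ambiguous),
              if (x$anchored) "" else "not ",
              if (x$budget_stop) ", budget hit" else ""))
  invisible(x)
}

#' Correct a whole read set
#'
#' Applies [correct_read()] to every read. Output rows are in input order
#' and no read is discarded or trimmed. `workers` is accepted for interface
#' compatibility; every per-read decision is a pure function of the read
#' and the (read-only) filter, so the output is identical for any worker
#' count, and execution here is sequential.
#'
#' @param reads Read tibble (`id`, `seq`, optionally `qual`).
#' @param filterB Solid k-mer filter (read-only in this pass).
#' @param k k-mer length.
#' @param qthresh A [quality_thresholds()] object or `NULL`.
#' @param limit Correction budget per k-window (default 4).
#' @param workers Ignored beyond validation; see Details.
#' @return A list of class `dataset_correction`: `reads` (tibble `id`,
#'   `seq` (corrected), `qual`, `anchored`, `budget_stop`), `edits` (tibble
#'   `read`, `id`, `pos`, `from`, `to`, `weight`), `ambiguous` (tibble
#'   `read`, `id`, `pos`).
#' @export
correct_reads <- function(reads, filterB, k, qthresh = NULL, limit = 4,
                          workers = 1L) {
  stopifnot(is.data.frame(reads), "seq" %in% names(reads),
            inherits(filterB, "kmer_set"), workers >= 1)
  quals <- if ("qual" %in% names(reads)) reads$qual else NULL
  ids <- if ("id" %in% names(reads)) reads$id else as.character(seq_len(nrow(reads)))
  off <- if (is.null(qthresh)) 33L else qthresh$phred_offset
  r <- .pass3_cpp(reads$seq, quals, as.integer(k), filterB$ptr,
                  .cutoff_int(qthresh), as.integer(off), limit)
  out <- list(
    reads = tibble::tibble(
      id = ids, seq = r$seq,
      qual = if (is.null(quals)) NA_character_ else quals,
      anchored = r$anchored, budget_stop = r$budget_stop
    ),
    edits = tibble::tibble(read = r$edit_read, id = ids[r$edit_read],
                           pos = r$edit_pos, from = as.character(r$edit_from),
                           to = as.character(r$edit_to),
                           weight = r$edit_weight),
    ambiguous = tibble::tibble(read = r$ambig_read, id = ids[r$ambig_read],
                               pos = r$ambig_pos)
  )
  class(out) <- "dataset_correction"
  out
}

#' @export
print.dataset_correction <- function(x, ...) {
  cat(sprintf(
    "<dataset_correction> %d reads, %d edits, %d ambiguous positions, %d unanchored reads\n",
    nrow(x$reads), nrow(x$edits), nrow(x$ambiguous), sum(!x$reads$anchored)
  ))
  invisible(x)
}

#' @export
tidy.dataset_correction <- function(x, ...) x$edits

#' @export
glance.dataset_correction <- function(x, ...) {
  tibble::tibble(
    reads = nrow(x$reads),
    edits = nrow(x$edits),
    edited_reads = length(unique(x$edits$read)),
    ambiguous_positions = nrow(x$ambiguous),
    unanchored_reads = sum(!x$reads$anchored),
    budget_stops = sum(x$reads$budget_stop)
  )
}
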