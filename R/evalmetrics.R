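#' Score corrections against the truth ledger
#'
#' Per-position accounting over all positions of all reads:
#' \describe{
#'   \item{TP}{an injected error corrected to the true base}
#'   \item{FP}{a substitution applied at an error-free position}
#'   \item{FN}{an injected error left uncorrected, or corrected to a wrong
#'     base (a wrong substitution at an error position counts once, as FN,
#'     never as FP)}
#' }
#' and the derived summaries `recall = TP / (TP + FN)`, `precision = TP /
#' (TP + FP)`, `f_score` (their harmonic mean) and `gain = (TP - FP) / (TP
#' + FN)` — the net fraction of errors removed after penalizing spurious
#' edits. `gain <= recall`, with equality exactly when `FP = 0`.
#'
#' @param corrected A [correct_reads()] or [run_correction()] result, or a
#'   plain edits tibble with columns `read`, `pos`, `to` (1-based
#'   positions, read ordinals matching the ledger's `read` column).
#' @param truth Truth ledger tibble (`read`, `pos`, `true`, `observed`),
#'   as produced by [sim_reads()].
#' @return Object of class `eval_summary`: list with `TP`, `FP`, `FN`,
#'   `recall`, `precision`, `f_score`, `gain`.
#' @examples
#' truth <- tibble::tibble(read = 1:3, pos = 5L, true = "A", observed = "G")
#' edits <- tibble::tibble(read = 1:2, pos = 5L, to = c("A", "C"))
#' glance(classify_corrections(edits, truth))
#' @export
classify_corrections <- function(corrected, truth) {
  edits <- if (inherits(corrected, c("dataset_correction", "correction_run")))
    corrected$edits else corrected
  stopifnot(is.data.frame(edits), all(c("read", "pos", "to") %in% names(edits)),
            is.data.frame(truth),
            all(c("read", "pos", "true") %in% names(truth)))
  if (inherits(corrected, c("dataset_correction", "correction_run")) &&
      !is.null(corrected$reads) && "id" %in% names(truth) && nrow(truth) > 0) {
    ledger_ids <- corrected$reads$id[truth$read]
    if (any(ledger_ids != truth$id))
      stop("read id mismatch between corrected reads and truth ledger")
  }
  j <- dplyr::full_join(
    dplyr::select(edits, "read", "pos", "to"),
    dplyr::select(truth, "read", "pos", "true"),
    by = c("read", "pos")
  )
  TP <- sum(!is.na(j$true) & !is.na(j$to) & j$true == j$to)
  FP <- sum(is.na(j$true) & !is.na(j$to))
  FN <- nrow(truth) - TP
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f_score <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  gain <- if (TP + FN > 0) (TP - FP) / (TP + FN) else NA_real_
  out <- list(TP = TP, FP = FP, FN = FN, recall = recall,
              precision = precision, f_score = f_score, gain = gain)
  class(out) <- "eval_summary"
  out
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> TP=%d FP=%d FN=%d | recall %.2f%%, precision %.2f%%, F %.2f%%, gain %.2f%%\n",
    x$TP, x$FP, x$FN, 100 * x$recall, 100 * x$precision, 100 * x$f_score,
    100 * x$gain
  ))
  invisible(x)
}

#' @export
tidy.eval_summary <- function(x, ...) {
  tibble::tibble(
    metric = c("TP", "FP", "FN", "recall", "precision", "f_score", "gain"),
    value = c(x$TP, x$FP, x$FN, x$recall, x$precision, x$f_score, x$gain)
  )
}

#' @export
glance.eval_summary <- function(x, ...) {
  tibble::tibble(TP = x$TP, FP = x$FP, FN = x$FN, recall = x$recall,
                 precision = x$precision, f_score = x$f_score, gain = x$gain)
}

#' Tabulate evaluation summaries
#'
#' One row per run with the four accuracy summaries as percentages rounded
#' to two decimals, ready for a report table.
#'
#' @param summaries List of [classify_corrections()] results.
#' @param labels Character vector of run labels (same length).
#' @return Tibble: `label`, `recall`, `precision`, `f_score`, `gain`
#'   (percent, 2 decimals). Zero rows when `summaries` is empty.
#' @export
eval_table <- function(summaries, labels = names(summaries)) {
  if (length(summaries) == 0)
    return(tibble::tibble(label = character(), recall = numeric(),
                          precision = numeric(), f_score = numeric(),
                          gain = numeric()))
  stopifnot(length(labels) == length(summaries))
  pct <- function(v) round(100 * v, 2)
  dplyr::bind_rows(lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    tibble::tibble(label = labels[i], recall = pct(s$recall),
                   precision = pct(s$precision), f_score = pct(s$f_score),
                   gain = pct(s$gain))
  }))
}

#' @param path Output TSV path.
#' @rdname eval_table
#' @export
eval_table_tsv <- function(summaries, labels = names(summaries), path) {
  readr::write_tsv(eval_table(summaries, labels), path)
  invisible(path)
}
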