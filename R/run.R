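#' Full three-pass error correction run
#'
#' Orchestrates the whole corrector over one or more read sources:
#'
#' 1. **Pass 1** subsamples k-mers (fraction `alpha`) into Bloom filter A.
#' 2. The subsample filter's occupancy gives the false-positive estimate
#'    `beta`; binomial trust thresholds are built from
#'    `p_star(alpha, beta)`, and the quality cutoff from the first reads'
#'    quality strings.
#' 3. **Pass 2** marks positions trusted/untrusted and stores every run of
#'    `k` consecutive trusted positions — the solid k-mers — in Bloom
#'    filter B.
#' 4. **Pass 3** greedily corrects substitution errors against B.
#'
#' Inputs may be in-memory read tibbles or FASTQ/FASTA paths; paths are
#' streamed in chunks so only the two Bloom filters are ever resident in
#' full. Paired-end inputs are given as two sources and share both
#' filters. Output order matches input order; no read is trimmed or
#' discarded. Given the same configuration and seed the run is fully
#' deterministic.
#'
#' @param input A read tibble ([read_fastx()] layout) or a file path, or a
#'   list of several such sources (e.g. the two ends of a paired-end run).
#' @param k k-mer length (1–31; default 23).
#' @param genome_size Genome-size proxy `G` used to size both filters.
#' @param alpha Subsampling fraction; exactly one of `alpha`/`coverage`.
#' @param coverage Average fold coverage, converted via
#'   [alpha_from_coverage()].
#' @param limit Correction budget per k-window (default 4).
#' @param seed Integer seed for all randomness.
#' @param bits_per_base Filter sizing: each filter gets
#'   `bits_per_base * genome_size` bits (default 12).
#' @param h Hash functions per filter (default 3).
#' @param block_bits Bloom filter block size (default 512).
#' @param quantile Trust-test tail mass (default 0.995).
#' @param phred_offset Quality encoding offset (default 33).
#' @param workers Accepted for interface compatibility; results are
#'   worker-count-independent by construction (execution is sequential).
#' @param out_dir Optional output directory; when given, corrected reads
#'   (`corrected.fastq`/`.fasta`), the edit ledger (`edits.tsv`) and a JSON
#'   run report (`report.json`) are written there.
#' @param chunk_size Reads per streamed chunk for path inputs (default
#'   250000).
#' @param keep_reads Keep corrected reads in the returned object (default
#'   TRUE for tibble input; set FALSE to rely on `out_dir` files only).
#' @return Object of class `correction_run`: list with `reads` (corrected
#'   tibble or `NULL`), `edits`, `ambiguous`, `report` (list: `alpha`,
#'   `beta`, `thresholds`, `quality`, filter occupancies, counts), `paths`.
#' @examples
#' g <- sim_genome(20000, seed = 2)
#' s <- sim_reads(g, coverage = 30, read_len = 80, mean_error = 0.01, seed = 2)
#' run <- run_correction(s$reads, k = 17, genome_size = 20000, coverage = 30,
#'                       seed = 2)
#' glance(run)
#' @export
run_correction <- function(input, k = 23L, genome_size, alpha = NULL,
                           coverage = NULL, limit = 4, seed = 1L,
                           bits_per_base = 12, h = 3L, block_bits = 512L,
                           quantile = 0.995, phred_offset = 33L,
                           workers = 1L, out_dir = NULL,
                           chunk_size = 250000L, keep_reads = NULL) {
  if (is.null(alpha) == is.null(coverage))
    stop("give exactly one of alpha or coverage")
  if (!is.null(coverage)) alpha <- alpha_from_coverage(coverage)
  stopifnot(k >= 1, k <= 31, genome_size >= 1, alpha > 0, alpha <= 1)
  sources <- if (is.data.frame(input) || is.character(input)) list(input)
             else input
  if (is.null(keep_reads)) keep_reads <- is.null(out_dir)
  m <- bits_per_base * genome_size
  A <- bloom_filter(m, h = h, block_bits = block_bits, seed = seed)
  B <- bloom_filter(m, h = h, block_bits = block_bits,
                    seed = as.numeric(seed) + 1)

  # ---- pass 1: subsample into A -------------------------------------------
  n_reads <- 0
  source_reads <- numeric(length(sources))
  p1 <- list(windows_total = 0, windows_valid = 0, survivors = 0)
  qual_sample <- character(0)
  for (si in seq_along(sources)) {
    src_n <- 0
    .for_each_chunk(sources[[si]], chunk_size, function(chunk, off) {
      st <- sample_kmers(chunk, k, alpha, A, seed = seed,
                         read_offset = n_reads + off)
      src_n <<- src_n + nrow(chunk)
      p1$windows_total <<- p1$windows_total + st$windows_total
      p1$windows_valid <<- p1$windows_valid + st$windows_valid
      p1$survivors <<- p1$survivors + st$survivors
      if (length(qual_sample) < 1e6 && "qual" %in% names(chunk)) {
        q <- chunk$qual[!is.na(chunk$qual)]
        qual_sample <<- c(qual_sample, utils::head(q, 1e6 - length(qual_sample)))
      }
    })
    source_reads[si] <- src_n
    n_reads <- n_reads + src_n
  }
  beta <- estimate_fp(A)
  thresholds <- trust_thresholds(k, p_star(alpha, beta), quantile = quantile)
  qthresh <- if (length(qual_sample) > 0)
    quality_thresholds(tibble::tibble(qual = qual_sample),
                       phred_offset = phred_offset)
  else {
    qt <- list(t1 = NA_integer_, t2 = NA_integer_, cutoff = -Inf,
               sample_size = 0L, phred_offset = as.integer(phred_offset))
    class(qt) <- "quality_thresholds"
    qt
  }

  # ---- pass 2: trust test, solid k-mers into B ----------------------------
  p2 <- list(solid_added = 0, trusted_positions = 0, positions = 0)
  for (src in sources) {
    .for_each_chunk(src, chunk_size, function(chunk, off) {
      st <- build_solid_filter(chunk, A, thresholds, qthresh, B)
      p2$solid_added <<- p2$solid_added + st$solid_added
      p2$trusted_positions <<- p2$trusted_positions + st$trusted_positions
      p2$positions <<- p2$positions + st$positions
    })
  }

  # ---- pass 3: greedy correction ------------------------------------------
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  all_reads <- list()
  all_edits <- list()
  all_ambig <- list()
  first_write <- TRUE
  read_base <- 0
  for (si in seq_along(sources)) {
    .for_each_chunk(sources[[si]], chunk_size, function(chunk, off) {
      res <- correct_reads(chunk, B, k, qthresh = qthresh, limit = limit,
                           workers = workers)
      res$edits$read <- res$edits$read + read_base + off
      res$ambiguous$read <- res$ambiguous$read + read_base + off
      all_edits[[length(all_edits) + 1]] <<- res$edits
      all_ambig[[length(all_ambig) + 1]] <<- res$ambiguous
      if (keep_reads) all_reads[[length(all_reads) + 1]] <<- res$reads
      if (!is.null(out_dir)) {
        has_q <- !any(is.na(res$reads$qual))
        out_path <- file.path(out_dir,
                              if (has_q) "corrected.fastq" else "corrected.fasta")
        if (has_q) write_fastq(res$reads, out_path, append = !first_write)
        else write_fasta(res$reads, out_path, append = !first_write)
        paths["corrected"] <<- out_path
        first_write <<- FALSE
      }
    })
    read_base <- read_base + source_reads[si]
  }
  edits <- if (length(all_edits)) dplyr::bind_rows(all_edits) else
    tibble::tibble(read = integer(), id = character(), pos = integer(),
                   from = character(), to = character(), weight = numeric())
  ambiguous <- if (length(all_ambig)) dplyr::bind_rows(all_ambig) else
    tibble::tibble(read = integer(), id = character(), pos = integer())

  report <- list(
    k = as.integer(k), genome_size = genome_size, alpha = alpha,
    beta = beta, quantile = quantile, limit = limit,
    seed = as.integer(seed), reads = n_reads,
    thresholds = thresholds,
    quality = qthresh,
    pass1 = p1, pass2 = p2,
    occupancy_a = bloom_stats(A)$occupancy,
    occupancy_b = bloom_stats(B)$occupancy,
    edits = nrow(edits), ambiguous = nrow(ambiguous)
  )
  if (!is.null(out_dir)) {
    paths["edits"] <- file.path(out_dir, "edits.tsv")
    readr::write_tsv(edits, paths["edits"])
    paths["report"] <- file.path(out_dir, "report.json")
    rep_json <- report
    rep_json$thresholds <- as.data.frame(thresholds)
    rep_json$quality <- unclass(qthresh)
    rep_json$quality$cutoff <- if (is.finite(qthresh$cutoff)) qthresh$cutoff else NULL
    jsonlite::write_json(rep_json, paths["report"], auto_unbox = TRUE,
                         digits = NA)
  }
  out <- list(
    reads = if (keep_reads) dplyr::bind_rows(all_reads) else NULL,
    edits = edits, ambiguous = ambiguous, report = report,
    filters = list(A = A, B = B), paths = paths
  )
  class(out) <- "correction_run"
  out
}

#' @export
print.correction_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<correction_run> %s reads | k=%d alpha=%.4g beta=%.3g\n",
              format(r$reads, big.mark = ","), r$k, r$alpha, r$beta))
  cat(sprintf("  filter occupancy: A %.2f%%, B %.2f%%\n",
              100 * r$occupancy_a, 100 * r$occupancy_b))
  cat(sprintf("  %s edits applied, %s ambiguous positions\n",
              format(r$edits, big.mark = ","),
              format(r$ambiguous, big.mark = ",")))
  invisible(x)
}

#' @export
tidy.correction_run <- function(x, ...) x$edits

#' @export
glance.correction_run <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    reads = r$reads, k = r$k, alpha = r$alpha, beta = r$beta,
    occupancy_a = r$occupancy_a, occupancy_b = r$occupancy_b,
    solid_kmers = r$pass2$solid_added,
    trusted_fraction = r$pass2$trusted_positions / r$pass2$positions,
    edits = r$edits, ambiguous = r$ambiguous
  )
}
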