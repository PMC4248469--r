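#' Simulate a genome (optionally diploid)
#'
#' Draws an i.i.d. uniform A/C/G/T sequence. In diploid mode a second
#' haplotype is produced by substituting a random different base at a
#' Bernoulli(`het_rate`) subset of positions — heterozygous SNPs whose
#' overlapping k-mers carry roughly half the coverage of homozygous ones.
#'
#' @param length Genome length in bases.
#' @param seed Integer seed; identical seeds reproduce the genome exactly.
#' @param diploid Produce two haplotypes.
#' @param het_rate Heterozygous SNP rate (default 0.001, i.e. 0.1% of
#'   positions).
#' @return Object of class `sim_genome`: list with `haplotypes` (character
#'   vector of 1 or 2 sequences), `het_sites` (1-based positions differing
#'   between haplotypes), `length`.
#' @export
sim_genome <- function(length, seed = 1L, diploid = FALSE, het_rate = 0.001) {
  stopifnot(length >= 1, het_rate >= 0, het_rate < 1)
  g1 <- .random_dna_cpp(as.numeric(length), as.numeric(seed))
  haps <- g1
  sites <- integer(0)
  if (diploid) {
    h2 <- .het_haplotype_cpp(g1, het_rate, as.numeric(seed) + 7919)
    haps <- c(g1, h2$seq)
    sites <- h2$het_sites
  }
  out <- list(haplotypes = haps, het_sites = sites, length = as.numeric(length))
  class(out) <- "sim_genome"
  out
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s bp, %d haplotype(s), %d het site(s)\n",
              format(x$length, big.mark = ","), length(x$haplotypes),
              length(x$het_sites)))
  invisible(x)
}

#' Simulate short reads with a 3'-weighted error ramp
#'
#' Emulates uniform single-end short-read sequencing: `round(coverage *
#' genome_length / read_len)` reads of fixed length, start positions and
#' strands uniform, and (in diploid mode) each read's haplotype uniform, so
#' both genomes contribute equal read numbers in expectation.
#'
#' Substitution errors are injected with a per-position probability rising
#' linearly from `mean_error / 2` at the 5' end to `3 * mean_error / 2` at
#' the 3' end — the mean is exactly `mean_error` while errors concentrate
#' toward the 3' end, as in real Illumina data. Phred qualities are derived
#' from the true per-position error probabilities (`round(-10 * log10 p)`,
#' clamped to `[2, 40]`), so the quality strings are consistent with the
#' injected error process. Every injected error is recorded in the truth
#' ledger.
#'
#' @param genome A [sim_genome()] (or a plain character vector of one or
#'   two haplotype sequences).
#' @param coverage Average fold coverage.
#' @param read_len Read length (default 101).
#' @param mean_error Mean per-base substitution error rate (default 0.01).
#' @param seed Integer seed; `(config, seed)` determines the output
#'   byte-for-byte.
#' @return Object of class `sim_reads`: list with
#'   \describe{
#'     \item{reads}{tibble `id`, `seq`, `qual`}
#'     \item{truth}{tibble `read` (ordinal), `id`, `pos`, `true`, `observed`
#'       — one row per injected error}
#'     \item{layout}{tibble `id`, `start`, `hap`, `rev` (sampling ground
#'       truth)}
#'     \item{config}{the simulation parameters, including the ramp
#'       endpoints `r5`, `r3`}
#'   }
#' @examples
#' g <- sim_genome(2000, seed = 4)
#' s <- sim_reads(g, coverage = 5, read_len = 50, mean_error = 0.02, seed = 4)
#' nrow(s$truth) / (nrow(s$reads) * 50)  # close to 0.02
#' @export
sim_reads <- function(genome, coverage, read_len = 101L, mean_error = 0.01,
                      seed = 1L) {
  haps <- if (inherits(genome, "sim_genome")) genome$haplotypes else genome
  stopifnot(is.character(haps), length(haps) %in% 1:2,
            coverage > 0, read_len >= 1, mean_error >= 0, mean_error < 2 / 3)
  glen <- nchar(haps[1])
  if (glen < read_len) stop("genome shorter than the read length")
  n_reads <- round(coverage * glen / read_len)
  r5 <- mean_error / 2
  r3 <- 3 * mean_error / 2
  sim <- .sim_reads_cpp(haps, n_reads, as.integer(read_len), r5, r3,
                        as.numeric(seed))
  ids <- sprintf("r%d", seq_len(n_reads))
  qual <- .ramp_quality(read_len, r5, r3)
  out <- list(
    reads = tibble::tibble(id = ids, seq = sim$seq,
                           qual = rep(qual, n_reads)),
    truth = tibble::tibble(read = sim$err_read, id = ids[sim$err_read],
                           pos = sim$err_pos,
                           true = as.character(sim$err_true),
                           observed = as.character(sim$err_obs)),
    layout = tibble::tibble(id = ids, start = sim$start, hap = sim$hap,
                            rev = sim$rev),
    config = list(coverage = coverage, read_len = as.integer(read_len),
                  mean_error = mean_error, r5 = r5, r3 = r3,
                  genome_length = glen, n_reads = n_reads,
                  diploid = length(haps) == 2, seed = seed)
  )
  class(out) <- "sim_reads"
  out
}

# Phred string implied by the linear error ramp (constant across reads).
.ramp_quality <- function(read_len, r5, r3, phred_offset = 33L) {
  p <- if (read_len == 1) (r5 + r3) / 2
       else r5 + (r3 - r5) * (seq_len(read_len) - 1) / (read_len - 1)
  q <- ifelse(p > 0, round(-10 * log10(p)), 40)
  q <- pmin(pmax(q, 2), 40)
  intToUtf8(q + phred_offset)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %s reads x %d bp (%.0fx of %s bp genome), %s injected errors\n",
    format(nrow(x$reads), big.mark = ","), x$config$read_len,
    x$config$coverage, format(x$config$genome_length, big.mark = ","),
    format(nrow(x$truth), big.mark = ",")
  ))
  invisible(x)
}

#' @export
tidy.sim_reads <- function(x, ...) x$truth

#' @export
glance.sim_reads <- function(x, ...) {
  total_bases <- nrow(x$reads) * x$config$read_len
  tibble::tibble(
    reads = nrow(x$reads), read_len = x$config$read_len,
    coverage = x$config$coverage, errors = nrow(x$truth),
    error_rate = nrow(x$truth) / total_bases,
    diploid = x$config$diploid
  )
}

#' Exact k-mer census of a genome
#'
#' Enumerates every valid window of the given sequence(s) and counts
#' distinct canonical k-mers and their multiplicities, by exact hash-set
#' enumeration. This is the evaluation oracle for solid-filter
#' completeness.
#'
#' @param genome A [sim_genome()] or character vector of sequences.
#' @param k k-mer length (1–31).
#' @return List: `distinct` (count), `multiplicity` (tibble `multiplicity`,
#'   `n_kmers`).
#' @examples
#' kmer_census("ACGTACGT", k = 4)$distinct
#' @export
kmer_census <- function(genome, k) {
  haps <- if (inherits(genome, "sim_genome")) genome$haplotypes else genome
  stopifnot(is.character(haps), k >= 1, k <= 31)
  r <- .kmer_census_cpp(haps, as.integer(k))
  mult <- tibble::tibble(multiplicity = r$multiplicity, n_kmers = r$n_kmers)
  list(distinct = r$distinct,
       multiplicity = dplyr::arrange(mult, .data$multiplicity))
}

#' Distinct canonical k-mer codes of a genome
#'
#' Two-bit codes (exact in doubles for `k <= 26`) of all distinct canonical
#' k-mers, optionally restricted to k-mers overlapping given positions —
#' used to measure what fraction of genomic (or heterozygous-site)
#' k-mers reached the solid filter.
#'
#' @inheritParams kmer_census
#' @param overlapping Optional list of 1-based position vectors (one per
#'   sequence); restricts to windows covering at least one position.
#' @return Numeric vector of canonical codes.
#' @export
genome_kmer_codes <- function(genome, k, overlapping = NULL) {
  haps <- if (inherits(genome, "sim_genome")) genome$haplotypes else genome
  stopifnot(is.character(haps), k >= 1, k <= 26)
  if (is.null(overlapping)) return(.distinct_codes_cpp(haps, as.integer(k)))
  stopifnot(is.list(overlapping), length(overlapping) == length(haps))
  .overlap_codes_cpp(haps, as.integer(k),
                     lapply(overlapping, as.integer))
}

#' Write simulation artifacts to disk
#'
#' Writes the genome haplotypes as FASTA, the reads as FASTQ (Phred+33) and
#' the truth ledger as (optionally gzipped) TSV.
#'
#' @param sim A [sim_reads()] object.
#' @param genome The [sim_genome()] the reads were drawn from.
#' @param dir Output directory (created if missing).
#' @param gzip Compress the ledger (default TRUE).
#' @return Named character vector of the paths written.
#' @export
sim_write <- function(sim, genome, dir, gzip = TRUE) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  haps <- if (inherits(genome, "sim_genome")) genome$haplotypes else genome
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    reads = file.path(dir, "reads.fastq"),
    truth = file.path(dir, if (gzip) "truth.tsv.gz" else "truth.tsv")
  )
  write_fasta(tibble::tibble(id = paste0("hap", seq_along(haps)), seq = haps),
              paths["genome"])
  write_fastq(sim$reads, paths["reads"])
  readr::write_tsv(sim$truth, paths["truth"])
  paths
}
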