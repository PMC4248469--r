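#' Read FASTQ/FASTA into a tibble
#'
#' Format is detected from the filename (`.fastq`/`.fq` vs `.fasta`/`.fa`/
#' `.fna`; a trailing `.gz` is handled transparently). Parsing is delegated
#' to Biostrings. FASTA records carry `NA` qualities, which disables
#' quality gating downstream.
#'
#' @param path Input file.
#' @param nrec,skip Optional record window (for chunked streaming).
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastx <- function(path, nrec = -1L, skip = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- .fastx_format(path)
  if (fmt == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      nrec = nrec, skip = skip,
                                      with.qualities = TRUE)
    qual <- unname(as.character(S4Vectors::mcols(x)$qualities))
    seqs <- unname(as.character(x))
    if (any(nchar(qual) != nchar(seqs)))
      stop("malformed FASTQ record: sequence and quality lengths differ (record ",
           which(nchar(qual) != nchar(seqs))[1] + skip, ")")
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta",
                                      nrec = nrec, skip = skip)
    seqs <- unname(as.character(x))
    qual <- rep(NA_character_, length(x))
  }
  tibble::tibble(id = .first_word(names(x)), seq = toupper(seqs), qual = qual)
}

.fastx_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(fastq|fq)$", p)) "fastq"
  else if (grepl("\\.(fasta|fa|fna)$", p)) "fasta"
  else stop("cannot infer format of '", path,
            "': expected .fastq/.fq or .fasta/.fa/.fna (optionally .gz)")
}

.first_word <- function(x) sub("\\s.*$", "", x)

#' Write reads as FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual` columns.
#' @param path Output path (a `.gz` suffix compresses).
#' @param append Append to an existing file (used by chunked runs).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, append = FALSE) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(is.na(reads$qual)))
    stop("reads carry no qualities; use write_fasta()")
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              append = append,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path, append = FALSE) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fasta", append = append,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Iterate over a read source in chunks: f(chunk_tibble, read_offset) for
# each chunk. Works for in-memory tibbles and for FASTQ/FASTA paths, so the
# three passes stream files without holding the whole dataset.
.for_each_chunk <- function(input, chunk_size, f) {
  if (is.data.frame(input)) {
    n <- nrow(input)
    off <- 0L
    while (off < n) {
      take <- min(chunk_size, n - off)
      f(input[(off + 1):(off + take), , drop = FALSE], off)
      off <- off + take
    }
    return(invisible(n))
  }
  off <- 0L
  repeat {
    chunk <- read_fastx(input, nrec = chunk_size, skip = off)
    if (nrow(chunk) == 0) break
    f(chunk, off)
    off <- off + nrow(chunk)
    if (nrow(chunk) < chunk_size) break
  }
  invisible(off)
}
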