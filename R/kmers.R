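#' Reverse complement of nucleotide sequences
#'
#' Vectorised Watson–Crick reverse complement over the full IUPAC alphabet
#' (`N` maps to `N`, `R` to `Y`, and so on). Lowercase input is uppercased.
#' The operation is an involution: `reverse_complement(reverse_complement(x))`
#' returns `x` (uppercased).
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACG", "AAAA"))
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  .rc_cpp(seq)
}

#' Canonicalize k-mers
#'
#' Returns, for each k-mer, the lexicographically prior of the k-mer and its
#' reverse complement (under `A < C < G < T`). Canonical k-mers make set
#' membership strand-symmetric: a k-mer and its reverse complement always
#' canonicalize to the same word, and the map is idempotent.
#'
#' Ambiguity codes are rejected; callers enumerate windows with
#' [kmer_windows()] and filter on its `valid` column first.
#'
#' @param word Character vector of k-mers over `{A,C,G,T}` (any common
#'   length `k <= 31`).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize(c("CGT", "ACG", "ACGT"))
#' @export
canonicalize <- function(word) {
  stopifnot(is.character(word))
  .canonicalize_cpp(word)
}

#' Two-bit k-mer codes
#'
#' Bijective packing of a k-mer into an integer with `A=0, C=1, G=2, T=3`,
#' leftmost base most significant, returned as a double. Doubles hold the
#' code exactly for `k <= 26` (52 bits); longer k-mers are carried in native
#' 64-bit form inside the compiled pipeline and are not exposed here.
#'
#' @param word Character vector of k-mers over `{A,C,G,T}`, `k <= 26`.
#' @return Numeric vector of codes.
#' @examples
#' encode2bit(c("AAA", "ACG"))
#' decode2bit(6, k = 3)
#' @export
encode2bit <- function(word) {
  stopifnot(is.character(word))
  .encode2bit_cpp(word)
}

#' @param code Numeric vector of two-bit codes.
#' @param k k-mer length used when encoding.
#' @rdname encode2bit
#' @export
decode2bit <- function(code, k) {
  stopifnot(is.numeric(code), length(k) == 1, k >= 1)
  .decode2bit_cpp(as.numeric(code), as.integer(k))
}

#' Enumerate k-mer windows of a read
#'
#' Returns the `|r| - k + 1` successive length-`k` windows of a sequence (an
#' empty tibble when the read is shorter than `k`). A window is `valid` only
#' when it consists exclusively of `A/C/G/T`; windows containing `N` or any
#' other ambiguity code are enumerated but flagged invalid, and are ignored
#' by every downstream filter operation.
#'
#' @param seq A single sequence string.
#' @param k Window length (1–31).
#' @return A tibble with columns `start` (1-based offset), `word`, `valid`.
#' @examples
#' kmer_windows("ACGTN", k = 3)
#' @export
kmer_windows <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1, k >= 1, k <= 31)
  w <- .kmer_windows_cpp(seq, as.integer(k))
  tibble::tibble(
    start = seq_along(w$word),
    word = as.character(w$word),
    valid = as.logical(w$valid)
  )
}
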