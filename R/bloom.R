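#' Pattern-blocked Bloom filter over canonical k-mers
#'
#' Creates an empty blocked Bloom filter. The bit array is divided into
#' blocks of `block_bits` bits; one hash selects the block for a key and `h`
#' further seeded hashes select bit offsets inside it, so every key touches
#' a single cache-line-sized region. `m` is rounded up to a whole number of
#' blocks. The filter is deterministic: two filters built with equal seeds
#' and insertion multisets have identical bit arrays.
#'
#' Bloom filters admit false positives (at a rate governed by `m`, `h` and
#' the number of distinct keys inserted; see [expected_fp_rate()]) but never
#' false negatives. Blocked filters run slightly above the unblocked
#' false-positive formula at equal size, the price of cache locality.
#'
#' @param m Requested number of bits (rounded up to a multiple of
#'   `block_bits`).
#' @param h Number of hash functions (default 3).
#' @param block_bits Bits per block; a power of two in `[64, 4096]`
#'   (default 512).
#' @param seed Integer seed for the hash family.
#' @return An object of class `c("bloom_filter", "kmer_set")`.
#' @seealso [kmer_hashset()] for an exact (false-positive-free) set with the
#'   same interface.
#' @examples
#' bf <- bloom_filter(2^14)
#' kmer_set_add(bf, c("ACGTACG", "TTTTTTT"))
#' kmer_set_contains(bf, c("ACGTACG", "CCCCCCC"))
#' @export
bloom_filter <- function(m, h = 3L, block_bits = 512L, seed = 1L) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1, h >= 1)
  obj <- list(ptr = .bloom_new_cpp(as.numeric(m), as.integer(h),
                                   as.integer(block_bits), as.numeric(seed)))
  class(obj) <- c("bloom_filter", "kmer_set")
  obj
}

#' Exact k-mer set
#'
#' A hash-set of canonical k-mer codes with the same add/contains interface
#' as [bloom_filter()], but exact: no false positives. Used as the oracle
#' stand-in for a Bloom filter in tests and for genome k-mer censuses.
#'
#' @param seq Optional character vector of sequences whose valid canonical
#'   k-mers seed the set.
#' @param k k-mer length (required when `seq` is given).
#' @return An object of class `c("kmer_hashset", "kmer_set")`.
#' @export
kmer_hashset <- function(seq = NULL, k = NULL) {
  obj <- list(ptr = .exact_new_cpp())
  class(obj) <- c("kmer_hashset", "kmer_set")
  if (!is.null(seq)) {
    stopifnot(!is.null(k))
    .set_add_seq_kmers_cpp(obj$ptr, seq, as.integer(k))
  }
  obj
}

#' Add k-mers to a k-mer set
#'
#' k-mers are canonicalized before insertion. Adding the same k-mer twice
#' changes no additional bits. Inserted k-mers are found by
#' [kmer_set_contains()] forever after (no false negatives).
#'
#' @param set A [bloom_filter()] or [kmer_hashset()].
#' @param kmers Character vector of k-mers over `{A,C,G,T}`, or a numeric
#'   vector of already-canonical two-bit codes when `codes = TRUE`.
#' @param codes Interpret `kmers` as numeric canonical codes.
#' @return The set, invisibly (modified in place).
#' @export
kmer_set_add <- function(set, kmers, codes = FALSE) {
  stopifnot(inherits(set, "kmer_set"))
  if (codes) .set_add_codes_cpp(set$ptr, as.numeric(kmers))
  else .set_add_words_cpp(set$ptr, as.character(kmers))
  invisible(set)
}

#' @rdname kmer_set_add
#' @return For `kmer_set_contains`, a logical vector of membership results
#'   (for a Bloom filter, subject to its false-positive rate).
#' @export
kmer_set_contains <- function(set, kmers, codes = FALSE) {
  stopifnot(inherits(set, "kmer_set"))
  if (codes) .set_contains_codes_cpp(set$ptr, as.numeric(kmers))
  else .set_contains_words_cpp(set$ptr, as.character(kmers))
}

#' Bloom filter occupancy and false-positive statistics
#'
#' @param set A [bloom_filter()].
#' @return One-row tibble: `m` (bits), `h`, `block_bits`, `bits_set`,
#'   `occupancy` (exact fraction of bits set), `inserts` (number of add
#'   calls), `est_fp` (occupancy-based false-positive estimate,
#'   `occupancy^h`).
#' @export
bloom_stats <- function(set) {
  stopifnot(inherits(set, "bloom_filter"))
  p <- .bloom_params_cpp(set$ptr)
  bits <- .set_bits_set_cpp(set$ptr)
  occ <- bits / p$m
  tibble::tibble(
    m = p$m, h = p$h, block_bits = p$block_bits,
    bits_set = bits, occupancy = occ,
    inserts = .set_n_add_cpp(set$ptr),
    est_fp = occ^p$h
  )
}

#' Closed-form Bloom filter false-positive rate
#'
#' The textbook approximation \eqn{(1 - e^{-hn/m})^h} for a filter of `m`
#' bits and `h` hash functions holding `n` distinct keys.
#'
#' @param n Distinct keys inserted.
#' @param m Filter size in bits.
#' @param h Number of hash functions.
#' @return Probability in `[0, 1]`.
#' @examples
#' expected_fp_rate(1e5, 2e6, 3)
#' @export
expected_fp_rate <- function(n, m, h) {
  stopifnot(all(n >= 0), all(m > 0), all(h >= 1))
  (1 - exp(-h * n / m))^h
}

#' Occupancy-based false-positive estimate
#'
#' Estimates a filter's realized false-positive probability as
#' \eqn{\rho^h} where \eqn{\rho} is the exact fraction of bits set. This is
#' the estimator behind the \eqn{\beta} term of the trust model: the
#' subsample filter's estimate feeds [p_star()] before thresholds are built.
#' An empty filter gives 0; a saturated one gives 1.
#'
#' @param set A [bloom_filter()].
#' @return Estimated false-positive probability.
#' @export
estimate_fp <- function(set) {
  stopifnot(inherits(set, "bloom_filter"))
  p <- .bloom_params_cpp(set$ptr)
  (.set_bits_set_cpp(set$ptr) / p$m)^p$h
}

#' @export
print.bloom_filter <- function(x, ...) {
  s <- bloom_stats(x)
  cat(sprintf(
    "<bloom_filter> m=%s bits (%d-bit blocks), h=%d | %.3f%% occupied, est. FP %.3g\n",
    format(s$m, big.mark = ","), s$block_bits, s$h, 100 * s$occupancy, s$est_fp
  ))
  invisible(x)
}

#' @export
print.kmer_hashset <- function(x, ...) {
  cat(sprintf("<kmer_hashset> %s distinct canonical k-mers\n",
              format(.exact_size_cpp(x$ptr), big.mark = ",")))
  invisible(x)
}

#' Number of distinct k-mers in an exact set
#'
#' @param set A [kmer_hashset()].
#' @return Count of distinct canonical k-mers.
#' @export
kmer_set_size <- function(set) {
  stopifnot(inherits(set, "kmer_hashset"))
  .exact_size_cpp(set$ptr)
}
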