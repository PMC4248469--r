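test_that("alpha = 1 sampling adds exactly the valid canonical windows", {
  A <- kmer_hashset()
  reads <- tibble::tibble(id = "r1", seq = "ACGTN", qual = NA_character_)
  st <- sample_kmers(reads, k = 3, alpha = 1, A, seed = 1)
  # windows ACG, CGT canonicalize to the same word; GTN skipped
  expect_equal(st$windows_total, 3)
  expect_equal(st$windows_valid, 2)
  expect_equal(kmer_set_size(A), 1)
  expect_true(kmer_set_contains(A, "ACG"))
  expect_error(sample_kmers(reads, 3, 0, A), "alpha")
})

test_that("survivor counts concentrate at alpha and are seed-stable", {
  set.seed(41)
  reads <- tibble::tibble(seq = replicate(1500, random_seq(90)))
  n_windows <- 1500 * (90 - 23 + 1)
  run <- function(seed) {
    A <- bloom_filter(2^21, seed = 1)
    sample_kmers(reads, 23, 0.1, A, seed = seed)$survivors
  }
  s1 <- run(17)
  # central 99% binomial interval
  bounds <- qbinom(c(0.005, 0.995), n_windows, 0.1)
  expect_gte(s1, bounds[1])
  expect_lte(s1, bounds[2])
  expect_equal(run(17), s1)        # same seed, same sample
  expect_false(run(18) == s1)      # different seed, different sample
})

test_that("sampling is independent of chunking via read_offset", {
  set.seed(42)
  reads <- tibble::tibble(seq = replicate(40, random_seq(60)))
  one <- kmer_hashset()
  sample_kmers(reads, 11, 0.3, one, seed = 5)
  split <- kmer_hashset()
  sample_kmers(reads[1:25, ], 11, 0.3, split, seed = 5, read_offset = 0)
  sample_kmers(reads[26:40, ], 11, 0.3, split, seed = 5, read_offset = 25)
  expect_equal(kmer_set_size(split), kmer_set_size(one))
})

test_that("fifth-percentile quality thresholds follow the ceil rule", {
  # 20 reads: 19 end in 'I' (Q40), one ends in '#' (Q2); ceil(0.05*20) = 1
  reads <- tibble::tibble(qual = c(rep("III", 19), "II#"))
  qt <- quality_thresholds(reads)
  expect_equal(qt$t1, 2)
  expect_equal(qt$t2, 40)
  expect_equal(qt$cutoff, 2)

  all_I <- quality_thresholds(tibble::tibble(qual = rep("II", 10)))
  expect_equal(all_I$t1, 40)
  expect_equal(all_I$cutoff, 39)  # min(t1, t2 - 1)

  fasta <- quality_thresholds(tibble::tibble(qual = rep(NA_character_, 5)))
  expect_equal(fasta$cutoff, -Inf)
  expect_error(quality_thresholds(tibble::tibble(qual = character(0))),
               "empty")
})

test_that("trust vector counts overlaps and hits correctly", {
  g <- "ACGTTGCAATGCCGTAAGGTCA"
  A <- kmer_hashset(g, k = 5)
  th1 <- trust_thresholds(5, 0)  # y_x = 1
  tp <- trust_positions(g, A, th1)
  L <- nchar(g)
  expect_true(all(tp$trusted))
  # x profile: ramps 1..k at the ends, k in the middle
  expect_equal(tp$x, pmin(pmin(tp$position, L - tp$position + 1), 5, L - 5 + 1))
  expect_equal(tp$hits, tp$x)  # every window of g is in A

  empty <- kmer_hashset()
  tp0 <- trust_positions(g, empty, th1)
  expect_false(any(tp0$trusted))  # hits = 0 < y_x >= 1

  short <- trust_positions("ACG", A, th1)
  expect_false(any(short$trusted))
  expect_equal(short$x, rep(0L, 3))
})

test_that("trust matches a brute-force window-membership count", {
  set.seed(43)
  k <- 11  # large enough that mutated windows almost surely miss the genome
  g <- random_seq(300)
  gk <- genome_kmers_ref(g, k)
  A <- kmer_hashset(g, k = k)
  for (ps in c(0, 0.3)) {  # y_x = 1 everywhere vs non-trivial thresholds
    th <- trust_thresholds(k, ps)
    read <- substr(g, 100, 160)
    pos <- 30
    bad <- read
    substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, pos, pos))[1]
    tp <- trust_positions(bad, A, th)
    words <- windows_ref(bad, k)
    in_a <- vapply(words, function(w) canon_ref(w) %in% gk, TRUE)
    oracle <- vapply(seq_len(nchar(bad)), function(i) {
      cover <- max(1, i - k + 1):min(i, length(words))
      sum(in_a[cover]) >= th$y[length(cover)]
    }, TRUE)
    expect_equal(tp$trusted, oracle)
    # the error position itself can never be trusted (all its windows are
    # error windows, absent from A in a repeat-free genome)
    expect_false(tp$trusted[pos])
  }
})

test_that("quality gate overrides k-mer support", {
  g <- "ACGTTGCAATGCCGTAAGGTCA"
  A <- kmer_hashset(g, k = 5)
  th <- trust_thresholds(5, 0)
  qt <- list(t1 = 30L, t2 = 30L, cutoff = 29L, sample_size = 1L,
             phred_offset = 33L)
  class(qt) <- "quality_thresholds"
  qual <- paste0(strrep("I", 10), strrep("#", nchar(g) - 10))  # Q40 then Q2
  tp <- trust_positions(g, A, th, qt, qual = qual)
  expect_true(all(tp$trusted[1:10]))
  expect_false(any(tp$trusted[11:nchar(g)]))
})

test_that("solid collection matches a brute-force scan over offsets", {
  set.seed(44)
  for (i in 1:10) {
    s <- random_seq(60)
    k <- 9
    trusted <- sample(c(TRUE, FALSE), 60, TRUE, prob = c(0.8, 0.2))
    B <- kmer_hashset()
    n <- collect_solid(s, trusted, k, B)
    # quadratic reference scan
    expected <- unique(vapply(
      Filter(function(o) all(trusted[o:(o + k - 1)]), seq_len(60 - k + 1)),
      function(o) canon_ref(substr(s, o, o + k - 1)), ""))
    expect_equal(n, length(expected))
    expect_equal(kmer_set_size(B), length(expected))
    if (length(expected)) expect_true(all(kmer_set_contains(B, expected)))
  }
})

test_that("fully trusted reads contribute all their windows", {
  s <- random_seq(40)
  B <- kmer_hashset()
  n <- collect_solid(s, rep(TRUE, 40), 11, B)
  expect_equal(n, length(genome_kmers_ref(s, 11)))
  B2 <- kmer_hashset()
  tr <- rep(TRUE, 40); tr[20] <- FALSE
  collect_solid(s, tr, 11, B2)
  # no window covering position 20 was added
  covering <- vapply(10:20, function(o) canon_ref(substr(s, o, o + 10)), "")
  expect_false(any(kmer_set_contains(B2, covering)))
})

test_that("error-free high-coverage data yields near-complete solid sets", {
  g <- sim_genome(50000, seed = 45)
  s <- sim_reads(g, coverage = 35, read_len = 101, mean_error = 0, seed = 45)
  run <- run_correction(s$reads, k = 23, genome_size = 50000, coverage = 35,
                        seed = 45)
  cen <- kmer_census(g, 23)
  codes <- genome_kmer_codes(g, 23)
  frac <- mean(kmer_set_contains(run$filters$B, codes, codes = TRUE))
  expect_gte(frac, 0.999)
})
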