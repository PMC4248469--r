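# toy repeat-free genome helper: resample until no canonical k-mer repeats
toy_genome <- function(len, k) {
  repeat {
    g <- random_seq(len)
    km <- vapply(windows_ref(g, k), canon_ref, "")
    if (!anyDuplicated(km)) return(g)
  }
}

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)
other_base <- function(b) other_bases(b)[1]

test_that("anchor finds the leftmost longest solid run", {
  set.seed(51)
  k <- 7
  g <- toy_genome(120, k)
  B <- kmer_hashset(g, k = k)
  read <- substr(g, 20, 80)
  expect_equal(find_anchor(read, B, k), c(1L, nchar(read) - k + 1L))
  expect_equal(length(find_anchor(read, kmer_hashset(), k)), 0)
  # engineered runs of known lengths: break windows by injecting errors
  set.seed(52)
  for (i in 1:15) {
    r <- substr(g, 10, 95)
    for (p in sample(seq(4, nchar(r) - 3), 3))
      r <- mutate_at(r, p, other_base(substr(r, p, p)))
    W <- nchar(r) - k + 1
    inb <- vapply(seq_len(W), function(o)
      canon_ref(substr(r, o, o + k - 1)) %in% genome_kmers_ref(g, k), TRUE)
    a <- find_anchor(r, B, k)
    ref <- ref_anchor(r, k, genome_kmers_ref(g, k))
    expect_equal(a, as.integer(ref))
    # leftmost maximal run property
    runs <- rle(inb)
    expect_equal(diff(a) + 1L, max(runs$lengths[runs$values]))
  }
})

test_that("substitution scoring counts consecutive solid windows", {
  set.seed(53)
  k <- 7
  g <- toy_genome(150, k)
  B <- kmer_hashset(g, k = k)
  read <- substr(g, 30, 90)
  pos <- 25
  truth <- substr(read, pos, pos)
  bad <- mutate_at(read, pos, other_base(truth))
  # restoring the true base recovers a full stretch of k windows
  expect_equal(score_substitution(bad, pos, truth, B, k), k)
  # scoring against the reference oracle for all four bases
  for (b in c("A", "C", "G", "T")) {
    got <- score_substitution(bad, pos, b, B, k)
    ref <- ref_stretch(mutate_at(bad, pos, b), pos - k + 1, k,
                       genome_kmers_ref(g, k))
    expect_equal(got, ref)
  }
  # a substitution creating an absent k-mer scores 0
  absent <- setdiff(c("A", "C", "G", "T"), truth)
  scores <- vapply(absent, function(b) score_substitution(bad, pos, b, B, k),
                   0L)
  expect_true(all(scores < k))
})

test_that("beyond-end extension resolves errors at the read tail", {
  set.seed(54)
  k <- 9
  len <- 61
  g <- toy_genome(200, k)
  gk <- genome_kmers_ref(g, k)
  B <- kmer_hashset(g, k = k)
  # pick a read placement where no single-base substitution at either tail
  # position collides with another genomic k-mer, so the true base is the
  # unique candidate whose window is in B at all
  clean_tail <- function(o) {
    read <- substr(g, o, o + len - 1)
    ok3 <- all(vapply(other_bases(substr(read, len, len)), function(b)
      !(canon_ref(paste0(substr(read, len - k + 1, len - 1), b)) %in% gk),
      TRUE))
    ok5 <- all(vapply(other_bases(substr(read, 1, 1)), function(b)
      !(canon_ref(paste0(b, substr(read, 2, k))) %in% gk), TRUE))
    ok3 && ok5
  }
  o <- Find(clean_tail, 30:120)
  expect_false(is.null(o))
  read <- substr(g, o, o + len - 1)
  truth <- substr(read, len, len)
  bad <- mutate_at(read, len, other_base(truth))
  res <- correct_read(bad, B, k)
  expect_equal(res$seq, read)
  expect_equal(res$edits$pos, len)
  expect_equal(res$edits$to, truth)
  # and at the 5' tail, mirrored through the reverse complement
  bad5 <- mutate_at(read, 1, other_base(substr(read, 1, 1)))
  res5 <- correct_read(bad5, B, k)
  expect_equal(res5$seq, read)
})

test_that("reads shorter than k or with no solid window pass through", {
  B <- kmer_hashset("ACGTTGCAATGCCGTA", k = 5)
  r <- correct_read("ACG", B, 5)
  expect_equal(r$seq, "ACG")
  expect_false(r$anchored)
  r2 <- correct_read(strrep("A", 30), B, 5)  # AAAAA not in B
  expect_equal(r2$seq, strrep("A", 30))
  expect_false(r2$anchored)
  expect_equal(nrow(r2$edits), 0)
})

test_that("error-free reads are returned unchanged", {
  set.seed(55)
  k <- 9
  g <- toy_genome(200, k)
  B <- kmer_hashset(g, k = k)
  for (i in 1:10) {
    o <- sample(1:(200 - 60), 1)
    read <- substr(g, o, o + 59)
    res <- correct_read(read, B, k)
    expect_equal(res$seq, read)
    expect_equal(nrow(res$edits), 0)
  }
})

test_that("engineered repeats yield ambiguity, not arbitrary edits", {
  k <- 5
  # a repeat context: both CCAAG and CCAAT are solid, neither extends, so
  # the final position of the read ties at stretch 1 and stays uncorrected
  read <- "ATGCACCAAG"
  Bwords <- unique(c(genome_kmers_ref(read, k), canon_ref("CCAAT")))
  B <- exact_set_of(Bwords)
  bad <- mutate_at(read, 10, "C")         # error at the last position
  res <- correct_read(bad, B, k)
  expect_equal(res$seq, bad)              # tie -> no edit
  expect_equal(nrow(res$edits), 0)
  expect_equal(res$ambiguous, 10L)
  ref <- ref_correct_read(bad, Bwords, k)
  expect_equal(res$seq, ref$seq)
  expect_equal(res$ambiguous, as.integer(unlist(ref$ambig)))
})

test_that("greedy correction equals the brute-force reference on random cases", {
  set.seed(56)
  k <- 9
  g <- toy_genome(400, k)
  gk <- genome_kmers_ref(g, k)
  B <- kmer_hashset(g, k = k)
  n_checked <- 0
  for (i in 1:60) {
    o <- sample(1:(400 - 55), 1)
    read <- substr(g, o, o + sample(40:55, 1))
    n_err <- sample(0:2, 1)
    bad <- read
    for (p in sample(seq_len(nchar(read)), n_err))
      bad <- mutate_at(bad, p, other_base(substr(bad, p, p)))
    res <- correct_read(bad, B, k)
    ref <- ref_correct_read(bad, gk, k)
    expect_equal(res$seq, ref$seq)
    expect_equal(res$anchored, ref$anchored)
    expect_equal(sort(res$ambiguous), sort(as.integer(unlist(ref$ambig))))
    expect_equal(nrow(res$edits), length(ref$edits))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("correction is idempotent with an exact solid set", {
  set.seed(57)
  k <- 9
  g <- toy_genome(300, k)
  B <- kmer_hashset(g, k = k)
  for (i in 1:15) {
    o <- sample(1:(300 - 60), 1)
    read <- substr(g, o, o + 59)
    bad <- read
    for (p in sample(10:50, 2))
      bad <- mutate_at(bad, p, other_base(substr(bad, p, p)))
    once <- correct_read(bad, B, k)
    twice <- correct_read(once$seq, B, k)
    expect_equal(twice$seq, once$seq)
    expect_equal(nrow(twice$edits), 0)
  }
})

test_that("the per-window budget caps applied edit weight", {
  set.seed(58)
  k <- 9
  g <- toy_genome(300, k)
  B <- kmer_hashset(g, k = k)
  read <- substr(g, 50, 150)
  # dense errors: 6 errors inside one k-window would exceed limit 4
  bad <- read
  err_pos <- c(40, 42, 44, 46, 48, 50)
  for (p in err_pos) bad <- mutate_at(bad, p, other_base(substr(bad, p, p)))
  res <- correct_read(bad, B, k, limit = 2)
  # post-hoc invariant: every k-window's applied weight sum <= limit
  w <- rep(0, nchar(bad))
  w[res$edits$pos] <- res$edits$weight
  for (s0 in seq_len(nchar(bad) - k + 1))
    expect_lte(sum(w[s0:(s0 + k - 1)]), 2)
  # with the default limit, the same read takes more edits
  res4 <- correct_read(bad, B, k, limit = 4)
  expect_gte(nrow(res4$edits), nrow(res$edits))
})

test_that("edit weights honour N and low-quality originals", {
  set.seed(59)
  k <- 9
  g <- toy_genome(200, k)
  B <- kmer_hashset(g, k = k)
  read <- substr(g, 40, 120)
  pos <- 40
  badN <- mutate_at(read, pos, "N")
  resN <- correct_read(badN, B, k)
  expect_equal(resN$seq, read)  # N restored from context
  expect_equal(resN$edits$weight, 0)

  qt <- list(t1 = 20L, t2 = 20L, cutoff = 19L, sample_size = 1L,
             phred_offset = 33L)
  class(qt) <- "quality_thresholds"
  qual <- strrep("I", nchar(read))          # Q40 everywhere
  substr(qual, pos, pos) <- "#"             # Q2 at the error
  bad <- mutate_at(read, pos, other_base(substr(read, pos, pos)))
  resq <- correct_read(bad, B, k, qual = qual, qthresh = qt)
  expect_equal(resq$edits$weight, 0.5)
  resq1 <- correct_read(bad, B, k)          # no qualities: weight 1
  expect_equal(resq1$edits$weight, 1)
})

test_that("dataset correction preserves order, length and determinism", {
  set.seed(60)
  k <- 9
  g <- toy_genome(500, k)
  B <- kmer_hashset(g, k = k)
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:40),
    seq = vapply(1:40, function(i) {
      o <- sample(1:(500 - 70), 1)
      r <- substr(g, o, o + 69)
      p <- sample(5:65, 1)
      mutate_at(r, p, other_base(substr(r, p, p)))
    }, ""),
    qual = strrep("I", 70)
  )
  res1 <- correct_reads(reads, B, k, workers = 1)
  res4 <- correct_reads(reads, B, k, workers = 4)
  expect_identical(res1$reads, res4$reads)
  expect_identical(res1$edits, res4$edits)
  expect_equal(res1$reads$id, reads$id)
  expect_equal(nchar(res1$reads$seq), nchar(reads$seq))
  empty <- correct_reads(reads[0, ], B, k)
  expect_equal(nrow(empty$reads), 0)
})
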