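test_that("genome simulation is reproducible and ACGT-only", {
  g1 <- sim_genome(5000, seed = 71)
  g2 <- sim_genome(5000, seed = 71)
  expect_identical(g1$haplotypes, g2$haplotypes)
  expect_false(identical(g1$haplotypes, sim_genome(5000, seed = 72)$haplotypes))
  expect_false(grepl("[^ACGT]", g1$haplotypes))
  # base composition roughly uniform
  tab <- table(strsplit(g1$haplotypes, "")[[1]])
  expect_true(all(abs(tab / 5000 - 0.25) < 0.05))
})

test_that("diploid mode injects heterozygous SNPs at the configured rate", {
  g0 <- sim_genome(2000, seed = 73, diploid = TRUE, het_rate = 0)
  expect_identical(g0$haplotypes[1], g0$haplotypes[2])
  expect_equal(length(g0$het_sites), 0)

  g <- sim_genome(1e6, seed = 73, diploid = TRUE, het_rate = 0.001)
  n_snp <- length(g$het_sites)
  bounds <- qbinom(c(0.005, 0.995), 1e6, 0.001)
  expect_gte(n_snp, bounds[1])
  expect_lte(n_snp, bounds[2])
  # haplotypes differ exactly at the recorded sites
  d <- which(strsplit(g$haplotypes[1], "")[[1]] !=
             strsplit(g$haplotypes[2], "")[[1]])
  expect_equal(d, g$het_sites)
})

test_that("error-free reads are exact substrings with an empty ledger", {
  g <- sim_genome(3000, seed = 74)
  s <- sim_reads(g, coverage = 10, read_len = 80, mean_error = 0, seed = 74)
  expect_equal(nrow(s$reads), round(10 * 3000 / 80))
  expect_equal(nrow(s$truth), 0)
  plus <- which(!s$layout$rev)[1:20]
  for (i in plus) {
    expect_equal(s$reads$seq[i],
                 substr(g$haplotypes, s$layout$start[i],
                        s$layout$start[i] + 79))
  }
  minus <- which(s$layout$rev)[1:10]
  for (i in minus) {
    expect_equal(s$reads$seq[i],
                 rc_ref(substr(g$haplotypes, s$layout$start[i],
                               s$layout$start[i] + 79)))
  }
})

test_that("injected error rate concentrates at the configured mean", {
  g <- sim_genome(2e5, seed = 75)
  s <- sim_reads(g, coverage = 35, read_len = 101, mean_error = 0.01,
                 seed = 75)
  total_bases <- nrow(s$reads) * 101
  rate <- nrow(s$truth) / total_bases
  expect_lt(abs(rate - 0.01), 0.0005)
  # ledger consistency: observed differs from true at every entry
  expect_true(all(s$truth$true != s$truth$observed))
  # the recorded observation matches the emitted read
  idx <- sample(nrow(s$truth), 200)
  expect_equal(substr(s$reads$seq[s$truth$read[idx]],
                      s$truth$pos[idx], s$truth$pos[idx]),
               s$truth$observed[idx])
})

test_that("errors grow toward the 3' end and qualities track the ramp", {
  g <- sim_genome(1e5, seed = 76)
  s <- sim_reads(g, coverage = 40, read_len = 101, mean_error = 0.02,
                 seed = 76)
  per_pos <- tabulate(s$truth$pos, nbins = 101) / nrow(s$reads)
  expect_gt(cor(seq_len(101), per_pos, method = "spearman"), 0.9)
  # 3' half carries more errors than the 5' half
  expect_gt(sum(per_pos[52:101]), sum(per_pos[1:50]))
  # qualities are phred-consistent with the ramp: q = round(-10 log10 p)
  q <- utf8ToInt(s$reads$qual[1]) - 33
  p <- 0.01 + (0.03 - 0.01) * (0:100) / 100
  expect_equal(q, pmin(pmax(round(-10 * log10(p)), 2), 40))
})

test_that("simulation is byte-identical under a fixed seed", {
  g <- sim_genome(10000, seed = 77)
  s1 <- sim_reads(g, coverage = 8, read_len = 60, mean_error = 0.01, seed = 9)
  s2 <- sim_reads(g, coverage = 8, read_len = 60, mean_error = 0.01, seed = 9)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- sim_reads(g, coverage = 8, read_len = 60, mean_error = 0.01, seed = 10)
  expect_false(identical(s1$reads$seq, s3$reads$seq))
})

test_that("diploid reads draw from both haplotypes evenly", {
  g <- sim_genome(50000, seed = 78, diploid = TRUE, het_rate = 0.001)
  s <- sim_reads(g, coverage = 20, read_len = 101, mean_error = 0, seed = 78)
  frac <- mean(s$layout$hap == 1)
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("k-mer census is exact on enumerable cases", {
  # brute-force enumeration: ACGTACGT 4-mers {ACGT, CGTA->TACG, GTAC, TACG}
  cen <- kmer_census("ACGTACGT", 4)
  expect_equal(cen$distinct, length(genome_kmers_ref("ACGTACGT", 4)))
  expect_equal(kmer_census(strrep("A", 7), 7)$distinct, 1)
  set.seed(79)
  for (i in 1:5) {
    g <- random_seq(200)
    cen <- kmer_census(g, 9)
    ref <- table(vapply(windows_ref(g, 9), canon_ref, ""))
    expect_equal(cen$distinct, length(ref))
    expect_lte(cen$distinct, 200 - 9 + 1)
    ref_mult <- as.data.frame(table(as.integer(ref)))
    expect_equal(cen$multiplicity$n_kmers,
                 as.numeric(ref_mult$Freq))
  }
  # codes interface agrees with the census
  g <- random_seq(300)
  expect_equal(length(genome_kmer_codes(g, 11)), kmer_census(g, 11)$distinct)
})
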