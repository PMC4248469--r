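---
title: "Counting-free error correction with paired Bloom filters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting-free error correction with paired Bloom filters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomcorrect)
```

## The model

Spectral error correction rests on one empirical fact about shotgun
sequencing: k-mers drawn from the genome recur in proportion to coverage,
while k-mers created by sequencing errors are each nearly unique. Classical
tools exploit this by counting every k-mer and thresholding the counts.
`bloomcorrect` gets the same separation without counts. If each k-mer
*occurrence* is kept independently with probability $\alpha$, a correct
k-mer with multiplicity $N$ is missing from the sample with probability
$(1-\alpha)^N$ — vanishing for high-multiplicity k-mers — while a weak
(error-derived) k-mer with multiplicity at most
$f(\alpha) = \max\{2,\, 0.2/\alpha\}$ appears with probability only

$$P(\alpha) = 1 - (1-\alpha)^{f(\alpha)}.$$

Membership in the sample is kept in a Bloom filter (filter A), which adds a
false-positive rate $\beta$; the effective probability that a weak k-mer
*appears* present is $P^*(\alpha) = P(\alpha) + \beta - \beta P(\alpha)$.
$\beta$ is estimated after the sampling pass as $\rho^h$ from A's realized
bit occupancy $\rho$ — the standard occupancy estimator — because the
thresholds below need the filter's actual state, not its design target.

A read position overlapped by $x$ k-mer windows ($1 \le x \le k$, smaller
near the read ends) is tested by counting how many of those windows are in
A. At an erroneous position every overlapping k-mer is weak, so the count
is stochastically dominated by $\mathrm{Binom}(x, P^*)$; the position is
called **trusted** when the count reaches

$$y_x = \min\Big\{y : \Pr\big[\mathrm{Binom}(x, P^*) \le y - 1\big] \ge q\Big\},
\qquad q = 0.995,$$

so erroneous positions pass with probability at most $1-q$. Runs of $k$
consecutive trusted positions define **solid** k-mers, collected into a
second Bloom filter (B). Correction then edits each read greedily toward B
(next section).

Because only the *sampled density* $\alpha K$ (with $K$ the total k-mers
sequenced) matters to A's load and to $P(\alpha)$ (which is nearly
scale-invariant for $\alpha \le 0.1$), choosing $\alpha = 7/C$ for coverage
$C$ makes memory, occupancy and accuracy nearly constant in depth. Both
filters are sized at a fixed $c \cdot G$ bits for a genome-size proxy $G$.

All k-mers are strand-canonicalized (the lexicographic minimum of the
k-mer and its reverse complement under $A<C<G<T$) before touching either
filter, so membership is strand-symmetric. Windows containing `N` or any
other ambiguity code count toward $x$ but can never hit A, so positions
near ambiguous bases lean untrusted — consistent with such windows never
being sampled in the first pass.

### The greedy walk

A read is anchored on its leftmost longest run of consecutive windows
present in B (no window in B: the read is returned untouched and flagged).
Scanning right from the anchor, the first window absent from B implicates
the base at its right end. All four nucleotides are scored by the number of
consecutive windows in B, starting at the failing window, that the
substitution produces — capped at $k$. When the count reaches the read end
unbroken it continues *virtually*: a step beyond the end counts only if
exactly one nucleotide extends the current $(k-1)$-suffix to a k-mer in B.
This resolves the otherwise-frequent ties at read tails, where only one or
two real windows cover the error. The unique maximizer (if any, with a
stretch of at least 1) is applied; on a tie the position is recorded
ambiguous and scanning resumes $k$ windows later. The left side is handled
by running the identical procedure on the reverse complement — legitimate
precisely because canonicalization makes B strand-blind.

For precision, applied edits carry weights — 0 when the original base is
`N`, 0.5 when its quality is at or below the quality cutoff, 1 otherwise —
and within any window of $k$ consecutive positions the applied weight may
not exceed a budget (default 4). An edit that would exceed it is withheld
and ends extension in that direction; edits already applied stand. The
budget is enforced causally, in discovery order, across both directions of
the walk.

### Quality gating

From the first million reads, the fifth-percentile quality at the last read
position ($t_1$) and at the first position ($t_2$) are taken, the
percentile being the smallest value with at least $\lceil 0.05 n \rceil$
values at or below it. Positions with quality at or below
$\min\{t_1, t_2 - 1\}$ are untrusted no matter their k-mer support, and
such bases also get the reduced 0.5 edit weight. FASTA input (no
qualities) disables the gate rather than inventing values.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 23 | k-mer length (1–31; 23 suits bacterial-scale genomes) |
| `genome_size` | — | genome-size proxy $G$, sizes both filters |
| `alpha` / `coverage` | — | subsampling fraction, or coverage from which $\alpha = \min(1, 7/C)$ |
| `bits_per_base` | 12 | $c$: each filter gets $c \cdot G$ bits |
| `h` | 3 | hash functions per filter |
| `block_bits` | 512 | Bloom block size in bits (a cache line) |
| `quantile` | 0.995 | tail mass of the trust test |
| `limit` | 4 | correction budget per k-window |
| `phred_offset` | 33 | FASTQ quality encoding |

The defaults for $c$ and $h$ are a deliberate economy: the trust
thresholds absorb A's realized false-positive rate through $P^*$, so the
filters need not be generously over-provisioned; 12 bits per genomic k-mer
at $h=3$ keeps $\beta$ in the low percent range at these loads.

## What the simulator emulates — and what it does not

`sim_genome()` / `sim_reads()` generate the study conditions under which
the package is tested: an i.i.d. uniform A/C/G/T genome; fixed-length
single-end reads (default 101 bp) with uniform start, strand and — in
diploid mode — haplotype; substitution errors whose per-base probability
rises linearly from $e/2$ at the 5′ end to $3e/2$ at the 3′ end, so the
mean is exactly the configured $e$ while errors concentrate 3′-ward as in
real Illumina data; Phred qualities derived from the true per-position
error probabilities, clamped to $[2, 40]$; and, in diploid mode,
heterozygous SNPs at 0.1% of positions with equal read sampling from both
haplotypes. Every injected error is recorded in a truth ledger, which is
what makes per-position recall/precision/gain computable exactly.

Deliberately absent: indels, repeat structure and compositional bias
(random genomes are nearly repeat-free at $k = 23$), coverage bias beyond
ploidy, sequencer-specific quality noise, and paired-end fragment geometry.
Two consequences matter when reading test results. First, because the
quality string is a deterministic function of position, the
fifth-percentile cutoff sits exactly at the ramp's tail values, so the
quality gate behaves like a sharp positional mask rather than the
probabilistic trim it is on real data. Second, passing accuracy here bounds
performance on repeat-free, uniformly covered genomes only; real genomes
with repeats shared at k-mer scale will see more ambiguity ties and more
near-miss corrections than the simulation exhibits.

## Numerical and design choices

- **Binomial CDF** by direct summation of pmf terms computed in log space
  (`lchoose` + logs), exponentiated and cumulated. For $x \le 31$ this is
  exact to double precision; no normal approximation, no continuity
  ambiguity. Degenerate inputs are handled explicitly: $P^* = 0$ gives
  $y_x = 1$, $P^* = 1$ gives $y_x = x + 1$ (nothing trustable).
- **Determinism without R's RNG in hot paths.** Hashing, subsampling and
  simulation use a SplitMix64 mixer. Pass-1 survival of a window is a pure
  function of (seed, read ordinal, window offset), so the sample is
  identical however the stream is chunked or ordered; the simulator's
  stream is keyed by the user seed, making output byte-identical per
  (config, seed). Worker counts cannot change any result — per-read
  decisions read only frozen filter state — so the `workers` argument is
  accepted for interface compatibility and execution is sequential.
- **Blocked Bloom layout.** One hash selects a block, `h` seeded hashes
  select offsets within it; all bits of a key share one cache line.
  Blocking trades a slightly elevated false-positive rate (about +12% over
  the unblocked closed form at default load and 512-bit blocks) for
  locality; the FP calibration tests measure against that expectation.
  `m` is rounded *up* to a whole number of blocks rather than rejected, so
  arbitrary sizes remain usable with at most one extra block of slack.
- **Two-bit codes at the R surface** are returned as doubles and therefore
  restricted to $k \le 26$ (52 bits); the compiled pipeline carries native
  64-bit codes and supports $k \le 31$ end to end. Rejecting $k > 26$ at
  `encode2bit()` beats silently rounding codes.
- **Positions are 1-based** everywhere in the R interface (windows, edit
  ledgers, truth ledgers), matching R convention.
- **Tie and resume rules.** A correction is applied only when exactly one
  base attains the maximum stretch; the original base participates
  harmlessly (it can never strictly win at a failing window). After a
  successful edit the scan resumes at the next window not in B; after an
  ambiguity it skips to the window past the implicated position. The
  anchor takes the leftmost longest run. Each of these rules breaks a
  genuine tie in the walk's definition; all were chosen for determinism
  and are exercised by the oracle-equivalence tests.
- **Qualities are never modified** by correction, and corrected reads are
  never trimmed or discarded; output length always equals input length.
- **Reads shorter than `k`** have no windows: all positions untrusted,
  read passed through unchanged.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite and the
acceptance script each finish in minutes on one CPU while keeping every
rate estimable: a 1-Mbp genome at 35× (≈350k reads) for the end-to-end
accuracy and solid-set completeness checks, 0.5-Mbp genomes for the
coverage-scaling sweep (20–140×) and the 70× diploid retention run, and
small constructed fixtures with exact (hash-set) k-mer sets for the
correction oracle. The method itself streams files in chunks and holds
only the two filters in memory, so genome-scale runs differ only in time.

## Known limitations

- The inverse-coverage rule stresses the trust test at its low-coverage
  end: at $C = 20$ ($\alpha = 0.35$), $f(\alpha)$ floors at 2 and
  $P(\alpha) \approx 0.58$, driving $y_x$ to within one or two of $x$ —
  near-end positions then require essentially *all* overlapping k-mers in
  A, and the few percent of correct k-mers thinned out of A by errors cost
  the solid filter a visible slice of the genome. The coverage-scaling
  test quantifies exactly this: filter A's occupancy is flat to a fraction
  of a percent across 20–140×, while filter B dips at 20×. Above ~35×
  ($\alpha \le 0.2$) the thresholds are tolerant and the dip vanishes.
- Heterozygous k-mers carry half coverage and are retained slightly below
  homozygous ones (measured by the diploid run in the acceptance script);
  other sources of non-uniform coverage (CNVs, targeted assays) would
  degrade similarly and are out of scope.
- Only substitutions are corrected; indel errors shift every downstream
  window and will typically surface as ambiguous or unanchored stretches.
- Canonicalization discards strand information, so strand-biased
  systematic errors cannot be told apart from coverage.
- `G`, `k` and `alpha` are user inputs; nothing is estimated from the
  reads.
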