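#include "core.h"
using namespace Rcpp;

// Uniform fixed-length read sampling with a 5'->3' linear substitution-error
// ramp. Per-read draws come from a dedicated SplitMix64 stream keyed by the
// user seed, so output is byte-identical for a given (config, seed) and does
// not touch R's RNG.
//
// genomes: one haplotype, or two in diploid mode (equal read counts drawn
// from each in expectation). Returns reads plus the ground-truth ledger of
// injected errors.
// [[Rcpp::export(name = ".sim_reads_cpp")]]
List sim_reads_cpp(CharacterVector genomes, double n_reads, int read_len,
                   double r5, double r3, double seed) {
  int nh = genomes.size();
  if (nh < 1 || nh > 2) stop("expected one or two haplotype sequences");
  std::vector<std::string> gen(nh);
  for (int i = 0; i < nh; i++) gen[i] = as<std::string>(genomes[i]);
  int L = read_len;
  for (int i = 0; i < nh; i++)
    if ((int)gen[i].size() < L) stop("genome shorter than the read length");
  int64_t n = (int64_t)n_reads;
  SplitMix rng(seed_from_double(seed) ^ 0x51A7D23ULL);

  // per-position error probabilities, linear from r5 at the 5' end to r3 at
  // the 3' end (mean is exactly (r5 + r3) / 2)
  std::vector<double> perr(L);
  for (int p = 0; p < L; p++)
    perr[p] = (L == 1) ? (r5 + r3) / 2 : r5 + (r3 - r5) * ((double)p / (L - 1));

  CharacterVector seq(n);
  IntegerVector start(n), hap(n);
  LogicalVector revstrand(n);
  std::vector<int> t_read, t_pos;
  std::vector<char> t_true, t_obs;
  std::string buf(L, 'A');
  for (int64_t i = 0; i < n; i++) {
    int hp = (nh == 2) ? (int)(rng.next() & 1) : 0;
    const std::string& g = gen[hp];
    uint64_t s0 = rng.bounded(g.size() - L + 1);
    bool rev = (rng.next() & 1) != 0;
    if (!rev) {
      for (int p = 0; p < L; p++) buf[p] = g[s0 + p];
    } else {
      for (int p = 0; p < L; p++) {
        char c = iupac_comp(g[s0 + L - 1 - p]);
        buf[p] = c ? c : 'N';
      }
    }
    for (int p = 0; p < L; p++) {
      if (perr[p] > 0 && rng.unif() < perr[p]) {
        int8_t b = base_code(buf[p]);
        if (b < 0) continue;  // no substitution model for ambiguous bases
        char nb = CODE_BASE[(b + 1 + (int)rng.bounded(3)) & 3];
        t_read.push_back((int)(i + 1));
        t_pos.push_back(p + 1);
        t_true.push_back(buf[p]);
        t_obs.push_back(nb);
        buf[p] = nb;
      }
    }
    seq[i] = buf;
    start[i] = (int)(s0 + 1);
    hap[i] = hp + 1;
    revstrand[i] = rev;
  }
  int ne = t_read.size();
  IntegerVector er(ne), ep(ne);
  CharacterVector et(ne), eo(ne);
  for (int i = 0; i < ne; i++) {
    er[i] = t_read[i]; ep[i] = t_pos[i];
    et[i] = std::string(1, t_true[i]);
    eo[i] = std::string(1, t_obs[i]);
  }
  return List::create(_["seq"] = seq, _["start"] = start, _["hap"] = hap,
                      _["rev"] = revstrand, _["err_read"] = er,
                      _["err_pos"] = ep, _["err_true"] = et,
                      _["err_obs"] = eo);
}

// i.i.d. uniform ACGT sequence (used by the genome simulator).
// [[Rcpp::export(name = ".random_dna_cpp")]]
std::string random_dna_cpp(double length, double seed) {
  int64_t n = (int64_t)length;
  SplitMix rng(seed_from_double(seed) ^ 0x6E0CABF3ULL);
  std::string s((size_t)n, 'A');
  for (int64_t i = 0; i < n; i++) s[i] = CODE_BASE[rng.bounded(4)];
  return s;
}

// Diploid second haplotype: substitute a random different base at a
// Bernoulli(het_rate) subset of positions. Returns the haplotype and the
// 1-based heterozygous positions.
// [[Rcpp::export(name = ".het_haplotype_cpp")]]
List het_haplotype_cpp(std::string genome, double het_rate, double seed) {
  SplitMix rng(seed_from_double(seed) ^ 0x4E7A11ULL);
  std::vector<int> sites;
  for (size_t i = 0; i < genome.size(); i++) {
    if (het_rate > 0 && rng.unif() < het_rate) {
      int8_t b = base_code(genome[i]);
      if (b < 0) continue;
      genome[i] = CODE_BASE[(b + 1 + (int)rng.bounded(3)) & 3];
      sites.push_back((int)i + 1);
    }
  }
  return List::create(_["seq"] = genome,
                      _["het_sites"] = IntegerVector(sites.begin(), sites.end()));
}
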