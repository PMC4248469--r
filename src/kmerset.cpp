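#include "core.h"
#include <unordered_map>
using namespace Rcpp;

// [[Rcpp::export(name = ".bloom_new_cpp")]]
SEXP bloom_new_cpp(double m, int h, int block_bits, double seed) {
  if (m < 1) stop("bloom filter: m must be positive");
  if (h < 1) stop("bloom filter: h must be >= 1");
  if (block_bits < 64 || block_bits > 4096 ||
      (block_bits & (block_bits - 1)) != 0)
    stop("bloom filter: block_bits must be a power of two in [64, 4096]");
  uint64_t mm = (uint64_t)m;
  uint64_t bb = (uint64_t)block_bits;
  mm = ((mm + bb - 1) / bb) * bb;  // round up to a whole number of blocks
  if (mm < bb) mm = bb;
  XPtr<KmerSet> p(new BloomKmerSet(mm, h, block_bits, seed_from_double(seed)),
                  true);
  return p;
}

// [[Rcpp::export(name = ".exact_new_cpp")]]
SEXP exact_new_cpp() {
  XPtr<KmerSet> p(new ExactKmerSet(), true);
  return p;
}

// [[Rcpp::export(name = ".set_is_bloom_cpp")]]
bool set_is_bloom_cpp(SEXP xp) { return get_set(xp)->is_bloom(); }

// [[Rcpp::export(name = ".bloom_params_cpp")]]
List bloom_params_cpp(SEXP xp) {
  KmerSet* s = get_set(xp);
  if (!s->is_bloom()) stop("not a bloom filter");
  BloomKmerSet* b = static_cast<BloomKmerSet*>(s);
  return List::create(_["m"] = (double)b->m, _["h"] = b->h,
                      _["block_bits"] = b->block_bits,
                      _["seed"] = (double)(int64_t)b->seed);
}

// [[Rcpp::export(name = ".set_bits_set_cpp")]]
double set_bits_set_cpp(SEXP xp) {
  KmerSet* s = get_set(xp);
  if (!s->is_bloom()) return (double)static_cast<ExactKmerSet*>(s)->s.size();
  return (double)static_cast<BloomKmerSet*>(s)->bits_set();
}

// [[Rcpp::export(name = ".set_n_add_cpp")]]
double set_n_add_cpp(SEXP xp) { return (double)get_set(xp)->n_add; }

// [[Rcpp::export(name = ".exact_size_cpp")]]
double exact_size_cpp(SEXP xp) {
  KmerSet* s = get_set(xp);
  if (s->is_bloom()) stop("not an exact k-mer set");
  return (double)static_cast<ExactKmerSet*>(s)->s.size();
}

static uint64_t canon_from_sexp_word(SEXP w, int idx) {
  const char* s = CHAR(w);
  int k = LENGTH(w);
  if (k < 1 || k > 31) stop("k-mer length must be in [1, 31] (element %d)", idx + 1);
  uint64_t f;
  if (!encode_word(s, k, f))
    stop("k-mer '%s' contains a non-ACGT character (element %d)", s, idx + 1);
  uint64_t r = rc_word_code(f, k);
  return f < r ? f : r;
}

// Adds canonical forms of the given k-mer words.
// [[Rcpp::export(name = ".set_add_words_cpp")]]
void set_add_words_cpp(SEXP xp, CharacterVector words) {
  KmerSet* s = get_set(xp);
  for (int i = 0; i < words.size(); i++) s->add(canon_from_sexp_word(words[i], i));
}

// [[Rcpp::export(name = ".set_contains_words_cpp")]]
LogicalVector set_contains_words_cpp(SEXP xp, CharacterVector words) {
  KmerSet* s = get_set(xp);
  LogicalVector out(words.size());
  for (int i = 0; i < words.size(); i++)
    out[i] = s->contains(canon_from_sexp_word(words[i], i));
  return out;
}

// Bit indices a key would touch (diagnostic; verifies blocked locality).
// [[Rcpp::export(name = ".bloom_key_bits_cpp")]]
NumericVector bloom_key_bits_cpp(SEXP xp, CharacterVector word) {
  KmerSet* s = get_set(xp);
  if (!s->is_bloom()) stop("not a bloom filter");
  BloomKmerSet* b = static_cast<BloomKmerSet*>(s);
  uint64_t code = canon_from_sexp_word(word[0], 0);
  uint64_t base = (mix64(code ^ b->seed_block) % b->n_blocks) *
                  (uint64_t)b->block_bits;
  NumericVector out(b->h);
  for (int j = 0; j < b->h; j++)
    out[j] = (double)(base + (mix64(code ^ b->hseed[j]) %
                              (uint64_t)b->block_bits));
  return out;
}

// Raw-code interface (codes assumed already canonical; exact for k <= 26).
// [[Rcpp::export(name = ".set_add_codes_cpp")]]
void set_add_codes_cpp(SEXP xp, NumericVector codes) {
  KmerSet* s = get_set(xp);
  for (double d : codes) s->add((uint64_t)d);
}

// [[Rcpp::export(name = ".set_contains_codes_cpp")]]
LogicalVector set_contains_codes_cpp(SEXP xp, NumericVector codes) {
  KmerSet* s = get_set(xp);
  LogicalVector out(codes.size());
  for (int i = 0; i < codes.size(); i++) out[i] = s->contains((uint64_t)codes[i]);
  return out;
}

// Add every valid canonical window of each sequence (used to build exact
// genome k-mer sets for oracles).
// [[Rcpp::export(name = ".set_add_seq_kmers_cpp")]]
double set_add_seq_kmers_cpp(SEXP xp, CharacterVector seqs, int k) {
  KmerSet* s = get_set(xp);
  double n = 0;
  for (int i = 0; i < seqs.size(); i++) {
    const char* str = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    KmerRoller roll(k);
    for (int j = 0; j < L; j++)
      if (roll.push(str[j])) { s->add(roll.canon()); n++; }
  }
  return n;
}

// Distinct canonical codes of all valid windows (k <= 26 keeps codes exact
// in doubles).
// [[Rcpp::export(name = ".distinct_codes_cpp")]]
NumericVector distinct_codes_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("distinct_codes: k must be in [1, 26]");
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < seqs.size(); i++) {
    const char* str = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    KmerRoller roll(k);
    for (int j = 0; j < L; j++)
      if (roll.push(str[j])) seen.insert(roll.canon());
  }
  NumericVector out(seen.size());
  int i = 0;
  for (uint64_t c : seen) out[i++] = (double)c;
  return out;
}

// Distinct canonical codes of windows overlapping any marked position
// (1-based positions, per sequence list entry).
// [[Rcpp::export(name = ".overlap_codes_cpp")]]
NumericVector overlap_codes_cpp(CharacterVector seqs, int k, List positions) {
  if (k < 1 || k > 26) stop("overlap_codes: k must be in [1, 26]");
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < seqs.size(); i++) {
    const char* str = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    IntegerVector pos = positions[i];
    std::vector<uint8_t> mark(L, 0);
    for (int p : pos)
      if (p >= 1 && p <= L) mark[p - 1] = 1;
    // prefix sums of marks to test window overlap quickly
    std::vector<int> cum(L + 1, 0);
    for (int j = 0; j < L; j++) cum[j + 1] = cum[j] + mark[j];
    KmerRoller roll(k);
    for (int j = 0; j < L; j++) {
      if (roll.push(str[j])) {
        int o = j - k + 1;
        if (cum[j + 1] - cum[o] > 0) seen.insert(roll.canon());
      }
    }
  }
  NumericVector out(seen.size());
  int i = 0;
  for (uint64_t c : seen) out[i++] = (double)c;
  return out;
}

// Exact census: distinct canonical k-mers and their multiplicities.
// [[Rcpp::export(name = ".kmer_census_cpp")]]
List kmer_census_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("kmer_census: k must be in [1, 31]");
  std::unordered_map<uint64_t, int> counts;
  for (int i = 0; i < seqs.size(); i++) {
    const char* str = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    KmerRoller roll(k);
    for (int j = 0; j < L; j++)
      if (roll.push(str[j])) counts[roll.canon()]++;
  }
  std::unordered_map<int, double> mult;
  for (auto& kv : counts) mult[kv.second] += 1;
  IntegerVector multiplicity(mult.size());
  NumericVector n_kmers(mult.size());
  int i = 0;
  for (auto& kv : mult) { multiplicity[i] = kv.first; n_kmers[i] = kv.second; i++; }
  return List::create(_["distinct"] = (double)counts.size(),
                      _["multiplicity"] = multiplicity,
                      _["n_kmers"] = n_kmers);
}
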