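#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_set>

// 2-bit nucleotide codes: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Watson-Crick complement over the full IUPAC alphabet (case-folded to
// upper); 0 for non-IUPAC characters.
static inline char iupac_comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': case 'U': case 'u': return 'A';
    case 'N': case 'n': return 'N';
    case 'R': case 'r': return 'Y';
    case 'Y': case 'y': return 'R';
    case 'S': case 's': return 'S';
    case 'W': case 'w': return 'W';
    case 'K': case 'k': return 'M';
    case 'M': case 'm': return 'K';
    case 'B': case 'b': return 'V';
    case 'D': case 'd': return 'H';
    case 'H': case 'h': return 'D';
    case 'V': case 'v': return 'B';
    default: return 0;
  }
}

// SplitMix64 finalizer: a well-mixed 64-bit hash, also used as a
// counter-based PRNG so every random decision is a pure function of
// (seed, counter) and independent of evaluation order.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(mix64(seed ^ 0x8C5FB1A7D4E92C3BULL)) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n) by 128-bit multiply (bias < 2^-64)
  uint64_t bounded(uint64_t n) {
    return (uint64_t)(((__uint128_t)next() * n) >> 64);
  }
};

static inline uint64_t seed_from_double(double s) {
  return (uint64_t)(int64_t)s;
}

// ---- k-mer codes -----------------------------------------------------------

// Encode word[0..k-1]; returns false if any non-ACGT character.
static inline bool encode_word(const char* w, int k, uint64_t& code) {
  uint64_t c = 0;
  for (int i = 0; i < k; i++) {
    int8_t b = base_code(w[i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static inline uint64_t rc_word_code(uint64_t code, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; i++) {
    r = (r << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return r;
}

static inline std::string decode_word(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = CODE_BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Canonical code of the window starting at s[o]; false when non-ACGT.
static inline bool window_canon(const char* s, int o, int k, uint64_t& code) {
  uint64_t f = 0, r = 0;
  for (int j = 0; j < k; j++) {
    int8_t b = base_code(s[o + j]);
    if (b < 0) return false;
    f = (f << 2) | (uint64_t)b;
    r |= (uint64_t)(3 - b) << (2 * j);
  }
  code = f < r ? f : r;
  return true;
}

// Rolling canonical-k-mer scanner over a sequence.
struct KmerRoller {
  int k;
  uint64_t mask, fwd, rev;
  int run;      // length of current valid-base run
  int shift;    // 2*(k-1)
  explicit KmerRoller(int k_) : k(k_), fwd(0), rev(0), run(0) {
    mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    shift = 2 * (k - 1);
  }
  // feed one base; returns true when a complete all-ACGT window ends here
  bool push(char c) {
    int8_t b = base_code(c);
    if (b < 0) { run = 0; fwd = 0; rev = 0; return false; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (run < k) run++;
    return run >= k;
  }
  uint64_t canon() const { return fwd < rev ? fwd : rev; }
};

// ---- k-mer set abstraction -------------------------------------------------

struct KmerSet {
  uint64_t n_add = 0;  // number of add() calls (not distinct keys)
  virtual ~KmerSet() {}
  virtual void add(uint64_t code) = 0;
  virtual bool contains(uint64_t code) const = 0;
  virtual bool is_bloom() const = 0;
};

// Pattern-blocked Bloom filter: one hash picks the block, h further seeded
// hashes pick bit offsets inside that block, so each key touches a single
// cache-line-sized region.
struct BloomKmerSet : KmerSet {
  uint64_t m;          // total bits (multiple of block_bits)
  int h;
  int block_bits;
  uint64_t seed;
  uint64_t n_blocks;
  uint64_t seed_block;
  std::vector<uint64_t> hseed;
  std::vector<uint64_t> words;

  BloomKmerSet(uint64_t m_, int h_, int bb, uint64_t seed_)
      : m(m_), h(h_), block_bits(bb), seed(seed_) {
    n_blocks = m / (uint64_t)block_bits;
    words.assign((m + 63) / 64, 0ULL);
    seed_block = mix64(seed ^ 0xB10CB10CB10CB10CULL);
    hseed.resize(h);
    for (int j = 0; j < h; j++) hseed[j] = mix64(seed_block + 0x9E37ULL * (j + 1));
  }
  void add(uint64_t code) override {
    n_add++;
    uint64_t base = (mix64(code ^ seed_block) % n_blocks) * (uint64_t)block_bits;
    for (int j = 0; j < h; j++) {
      uint64_t bit = base + (mix64(code ^ hseed[j]) % (uint64_t)block_bits);
      words[bit >> 6] |= 1ULL << (bit & 63);
    }
  }
  bool contains(uint64_t code) const override {
    uint64_t base = (mix64(code ^ seed_block) % n_blocks) * (uint64_t)block_bits;
    for (int j = 0; j < h; j++) {
      uint64_t bit = base + (mix64(code ^ hseed[j]) % (uint64_t)block_bits);
      if (!(words[bit >> 6] & (1ULL << (bit & 63)))) return false;
    }
    return true;
  }
  bool is_bloom() const override { return true; }
  uint64_t bits_set() const {
    uint64_t n = 0;
    for (uint64_t w : words) n += (uint64_t)__builtin_popcountll(w);
    return n;
  }
};

// Exact hash-set of k-mer codes: zero-false-positive stand-in used for
// oracles and the genome k-mer census.
struct ExactKmerSet : KmerSet {
  std::unordered_set<uint64_t> s;
  void add(uint64_t code) override { n_add++; s.insert(code); }
  bool contains(uint64_t code) const override { return s.count(code) != 0; }
  bool is_bloom() const override { return false; }
};

static inline KmerSet* get_set(SEXP xp) {
  Rcpp::XPtr<KmerSet> p(xp);
  return p.get();
}
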