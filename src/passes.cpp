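#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pass 1: k-mer subsampling into filter A.
//
// Each valid window survives independently with probability alpha. The
// Bernoulli draw is a pure function of (seed, read ordinal, window offset),
// so the sample is identical regardless of read order or threading.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sample_kmers_cpp")]]
List sample_kmers_cpp(CharacterVector seqs, int k, double alpha, double seed,
                      double ordinal_offset, SEXP filterA) {
  KmerSet* A = get_set(filterA);
  uint64_t sd = mix64(seed_from_double(seed) ^ 0x5A4D91E5ULL);
  double total = 0, valid = 0, kept = 0;
  for (int i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    uint64_t rd = mix64(sd + (uint64_t)(ordinal_offset + i));
    KmerRoller roll(k);
    for (int j = 0; j < L; j++) {
      bool ok = roll.push(s[j]);
      if (j >= k - 1) {
        total++;
        if (ok) {
          valid++;
          int offset = j - k + 1;
          double u = (mix64(rd + (uint64_t)offset) >> 11) * 0x1.0p-53;
          if (u < alpha) { A->add(roll.canon()); kept++; }
        }
      }
    }
  }
  return List::create(_["windows_total"] = total, _["windows_valid"] = valid,
                      _["survivors"] = kept);
}

// ---------------------------------------------------------------------------
// Pass 2: per-position trust test and solid k-mer collection.
//
// A position i is overlapped by x_i windows (invalid windows count toward
// x_i but can never hit filter A). It is trusted when the hit count reaches
// the binomial threshold y[x_i] and its quality exceeds the cutoff. Runs of
// k consecutive trusted positions define solid k-mers, added to filter B
// check-then-insert.
// ---------------------------------------------------------------------------

// Computes x, hits, trusted for one read. Returns W = number of windows.
static int trust_core(const char* s, int L, const char* q, int k, KmerSet* A,
                      const int* y, int cutoff, int phred_off,
                      std::vector<int>& xv, std::vector<int>& hv,
                      std::vector<uint8_t>& tv, std::vector<uint8_t>& inA,
                      std::vector<uint8_t>& wvalid) {
  xv.assign(L, 0);
  hv.assign(L, 0);
  tv.assign(L, 0);
  if (L < k) return 0;  // no windows: every position untrusted
  int W = L - k + 1;
  inA.assign(W, 0);
  wvalid.assign(W, 0);
  KmerRoller roll(k);
  for (int j = 0; j < L; j++) {
    bool ok = roll.push(s[j]);
    if (j >= k - 1 && ok) {
      int o = j - k + 1;
      wvalid[o] = 1;
      inA[o] = A->contains(roll.canon()) ? 1 : 0;
    }
  }
  std::vector<int> cum(W + 1, 0);
  for (int o = 0; o < W; o++) cum[o + 1] = cum[o] + inA[o];
  for (int i = 0; i < L; i++) {
    int lo = std::max(0, i - k + 1);
    int hi = std::min(i, W - 1);
    int x = hi - lo + 1;
    int hits = cum[hi + 1] - cum[lo];
    xv[i] = x;
    hv[i] = hits;
    bool qok = true;
    if (q) qok = ((int)(unsigned char)q[i] - phred_off) > cutoff;
    tv[i] = (hits >= y[x - 1] && qok) ? 1 : 0;
  }
  return W;
}

// [[Rcpp::export(name = ".trust_read_cpp")]]
List trust_read_cpp(std::string seq, SEXP qual, int k, SEXP filterA,
                    IntegerVector y, int cutoff, int phred_offset) {
  KmerSet* A = get_set(filterA);
  const char* q = NULL;
  std::string qs;
  if (qual != R_NilValue) {
    qs = as<std::string>(qual);
    if ((int)qs.size() != (int)seq.size())
      stop("quality string length differs from sequence length");
    q = qs.c_str();
  }
  std::vector<int> xv, hv;
  std::vector<uint8_t> tv, inA, wvalid;
  trust_core(seq.c_str(), seq.size(), q, k, A, &y[0], cutoff, phred_offset, xv,
             hv, tv, inA, wvalid);
  int L = seq.size();
  IntegerVector X(L), H(L);
  LogicalVector T(L);
  for (int i = 0; i < L; i++) { X[i] = xv[i]; H[i] = hv[i]; T[i] = tv[i]; }
  return List::create(_["x"] = X, _["hits"] = H, _["trusted"] = T);
}

// Adds solid k-mers of one read (given its trust vector) to B.
static double collect_core(const char* s, int L, int k,
                           const std::vector<uint8_t>& tv, KmerSet* B) {
  if (L < k) return 0;
  double added = 0;
  int trun = 0;  // run of trusted positions ending here
  KmerRoller roll(k);
  for (int j = 0; j < L; j++) {
    bool ok = roll.push(s[j]);
    trun = tv[j] ? trun + 1 : 0;
    if (j >= k - 1 && ok && trun >= k) {
      uint64_t c = roll.canon();
      if (!B->contains(c)) { B->add(c); added++; }
    }
  }
  return added;
}

// [[Rcpp::export(name = ".collect_solid_cpp")]]
double collect_solid_cpp(std::string seq, LogicalVector trusted, int k,
                         SEXP filterB) {
  int L = seq.size();
  if (trusted.size() != L) stop("trust vector length differs from sequence length");
  std::vector<uint8_t> tv(L);
  for (int i = 0; i < L; i++) tv[i] = trusted[i] ? 1 : 0;
  return collect_core(seq.c_str(), L, k, tv, get_set(filterB));
}

// Whole-dataset pass 2.
// [[Rcpp::export(name = ".pass2_cpp")]]
List pass2_cpp(CharacterVector seqs, SEXP quals, int k, SEXP filterA,
               IntegerVector y, int cutoff, int phred_offset, SEXP filterB) {
  KmerSet* A = get_set(filterA);
  KmerSet* B = get_set(filterB);
  bool has_q = quals != R_NilValue;
  CharacterVector qv;
  if (has_q) qv = as<CharacterVector>(quals);
  double solid_added = 0, trusted_total = 0, positions_total = 0;
  std::vector<int> xv, hv;
  std::vector<uint8_t> tv, inA, wvalid;
  for (int i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    const char* q = NULL;
    if (has_q && qv[i] != NA_STRING) {
      if (LENGTH(qv[i]) != L) stop("read %d: quality/sequence length mismatch", i + 1);
      q = CHAR(qv[i]);
    }
    trust_core(s, L, q, k, A, &y[0], cutoff, phred_offset, xv, hv, tv, inA,
               wvalid);
    for (int j = 0; j < L; j++) trusted_total += tv[j];
    positions_total += L;
    solid_added += collect_core(s, L, k, tv, B);
  }
  return List::create(_["solid_added"] = solid_added,
                      _["trusted_positions"] = trusted_total,
                      _["positions"] = positions_total);
}

// ---------------------------------------------------------------------------
// Pass 3: greedy substitution correction against filter B.
// ---------------------------------------------------------------------------

static bool window_in_B(const std::string& s, int o, int k, KmerSet* B) {
  uint64_t c;
  if (!window_canon(s.c_str(), o, k, c)) return false;
  return B->contains(c);
}

// Length of the consecutive-window stretch in B starting at window i
// (capped at k windows). When the stretch reaches the read end unbroken,
// counting continues virtually past the end: a virtual step counts only if
// exactly one nucleotide extends the current (k-1)-suffix to a k-mer in B.
static int stretch_len(const std::string& s, int i, int k, KmerSet* B) {
  int L = s.size();
  int W = L - k + 1;
  int c = 0;
  for (int o = i; o < W && c < k; o++) {
    if (window_in_B(s, o, k, B)) c++;
    else return c;
  }
  if (c >= k) return c;
  // all in-read windows from i were present; extend beyond the read end
  std::string suf = s.substr(L - k + 1);  // k-1 chars
  while (c < k) {
    int nmatch = 0;
    char hit = 0;
    uint64_t f0;
    if (!encode_word(suf.c_str(), k - 1, f0)) break;  // N in suffix
    for (int b = 0; b < 4; b++) {
      uint64_t f = (f0 << 2) | (uint64_t)b;
      uint64_t r = rc_word_code(f, k);
      if (B->contains(f < r ? f : r)) { nmatch++; hit = CODE_BASE[b]; }
    }
    if (nmatch != 1) break;
    c++;
    suf = suf.substr(1) + hit;
  }
  return c;
}

// [[Rcpp::export(name = ".score_substitution_cpp")]]
int score_substitution_cpp(std::string seq, int pos0, char base, int k,
                           SEXP filterB, bool leftward) {
  KmerSet* B = get_set(filterB);
  int L = seq.size();
  if (pos0 < 0 || pos0 >= L) stop("position out of range");
  if (leftward) {
    // mirror through the reverse complement; B is strand-symmetric
    std::string rc(L, 0);
    for (int j = 0; j < L; j++) {
      char c = iupac_comp(seq[L - 1 - j]);
      if (!c) stop("non-IUPAC character in read");
      rc[j] = c;
    }
    seq = rc;
    pos0 = L - 1 - pos0;
    char cb = iupac_comp(base);
    if (!cb) stop("invalid substitution base");
    base = cb;
  }
  int i = pos0 - k + 1;  // failing window whose last position is pos0
  if (i < 0) stop("position must be covered by a full window in the scan direction");
  seq[pos0] = base;
  return stretch_len(seq, i, k, B);
}

struct EditRec {
  int pos;      // 0-based, original orientation
  char from, to;
  double w;
};

struct CorrectScratch {
  std::vector<EditRec> edits;
  std::vector<int> ambig;   // 0-based positions, original orientation
  bool budget_stop = false;
  bool anchored = false;
};

// Largest weighted edit load over all length-k windows if an edit of weight
// w landed at position p (weights indexed in original orientation).
static bool budget_ok(const std::vector<double>& wts, int L, int k, int p,
                      double w, double limit) {
  int lo = std::max(0, p - k + 1);
  int hi = std::min(p, L - k);
  for (int s0 = lo; s0 <= hi; s0++) {
    double tot = w;
    int end = std::min(L - 1, s0 + k - 1);
    for (int j = s0; j <= end; j++) tot += wts[j];
    if (tot > limit) return false;
  }
  return true;
}

// Weight of a correction at original-orientation position p.
static double edit_weight(const std::string& orig, const std::string& qual,
                          int p, int cutoff, int phred_off) {
  if (base_code(orig[p]) < 0) return 0.0;  // 'N' or other ambiguity code
  if (!qual.empty() && ((int)(unsigned char)qual[p] - phred_off) <= cutoff)
    return 0.5;
  return 1.0;
}

// Rightward greedy walk over working string s (possibly the reverse
// complement of the read; fwd says which). Mutates s in place, records
// edits/ambiguities in original orientation, respects the shared budget.
static void walk_right(std::string& s, int start_w, int k, KmerSet* B,
                       const std::string& orig, const std::string& qual,
                       int cutoff, int phred_off, double limit, bool fwd,
                       std::vector<double>& wts, CorrectScratch& out) {
  int L = s.size();
  int W = L - k + 1;
  int i = start_w;
  while (i < W) {
    if (window_in_B(s, i, k, B)) { i++; continue; }
    int pos = i + k - 1;               // presumed error, s orientation
    int opos = fwd ? pos : L - 1 - pos;  // original orientation
    // score all four candidate bases
    char orig_here = s[pos];
    int best = -1, nbest = 0;
    char bbase = 0;
    for (int b = 0; b < 4; b++) {
      s[pos] = CODE_BASE[b];
      int sc = stretch_len(s, i, k, B);
      if (sc > best) { best = sc; nbest = 1; bbase = CODE_BASE[b]; }
      else if (sc == best) nbest++;
    }
    s[pos] = orig_here;
    if (nbest == 1 && best >= 1 && bbase != orig_here) {
      double w = edit_weight(orig, qual, opos, cutoff, phred_off);
      if (!budget_ok(wts, L, k, opos, w, limit)) {
        out.budget_stop = true;
        return;  // budget blocks this direction
      }
      char from = fwd ? orig_here : iupac_comp(orig_here);
      char to = fwd ? bbase : iupac_comp(bbase);
      s[pos] = bbase;
      wts[opos] += w;
      EditRec e; e.pos = opos; e.from = from; e.to = to; e.w = w;
      out.edits.push_back(e);
      // resume at the next window not in B (window i is now in B)
    } else {
      out.ambig.push_back(opos);
      i += k;  // resume at k_{i+k}
    }
  }
}

static void correct_one(std::string& seq, const std::string& qual, int k,
                        KmerSet* B, int cutoff, int phred_off, double limit,
                        CorrectScratch& out) {
  int L = seq.size();
  if (L < k) return;  // too short: untouched, unanchored
  int W = L - k + 1;
  // anchor: leftmost maximal run of consecutive windows present in B
  int best_b = -1, best_len = 0, run = 0;
  for (int o = 0; o < W; o++) {
    run = window_in_B(seq, o, k, B) ? run + 1 : 0;
    if (run > best_len) { best_len = run; best_b = o - run + 1; }
  }
  if (best_len == 0) return;  // nothing anchors this read
  out.anchored = true;
  int b = best_b, e = best_b + best_len - 1;
  std::string orig = seq;  // input bases drive edit weights
  std::vector<double> wts(L, 0.0);
  if (e + 1 < W) walk_right(seq, e + 1, k, B, orig, qual, cutoff, phred_off,
                            limit, true, wts, out);
  if (b > 0) {
    // mirror the leftward walk through the reverse complement
    std::string rc(L, 0);
    for (int j = 0; j < L; j++) {
      char c = iupac_comp(seq[L - 1 - j]);
      rc[j] = c ? c : 'N';
    }
    int start_w = (L - k - b) + 1;  // window left of the anchor, mirrored
    walk_right(rc, start_w, k, B, orig, qual, cutoff, phred_off, limit, false,
               wts, out);
    for (int j = 0; j < L; j++) {
      char c = iupac_comp(rc[L - 1 - j]);
      seq[j] = c ? c : 'N';
    }
  }
}

static List correct_result(const std::string& seq, const CorrectScratch& sc) {
  int ne = sc.edits.size();
  IntegerVector pos(ne);
  CharacterVector from(ne), to(ne);
  NumericVector w(ne);
  for (int i = 0; i < ne; i++) {
    pos[i] = sc.edits[i].pos + 1;  // 1-based at the R surface
    from[i] = std::string(1, sc.edits[i].from);
    to[i] = std::string(1, sc.edits[i].to);
    w[i] = sc.edits[i].w;
  }
  IntegerVector amb(sc.ambig.size());
  for (size_t i = 0; i < sc.ambig.size(); i++) amb[i] = sc.ambig[i] + 1;
  return List::create(_["seq"] = seq, _["pos"] = pos, _["from"] = from,
                      _["to"] = to, _["weight"] = w, _["ambiguous"] = amb,
                      _["budget_stop"] = sc.budget_stop,
                      _["anchored"] = sc.anchored);
}

// [[Rcpp::export(name = ".correct_read_cpp")]]
List correct_read_cpp(std::string seq, SEXP qual, int k, SEXP filterB,
                      int cutoff, int phred_offset, double limit) {
  KmerSet* B = get_set(filterB);
  std::string q;
  if (qual != R_NilValue) {
    q = as<std::string>(qual);
    if (q.size() != seq.size()) stop("quality/sequence length mismatch");
  }
  CorrectScratch sc;
  correct_one(seq, q, k, B, cutoff, phred_offset, limit, sc);
  return correct_result(seq, sc);
}

// [[Rcpp::export(name = ".find_anchor_cpp")]]
IntegerVector find_anchor_cpp(std::string seq, int k, SEXP filterB) {
  KmerSet* B = get_set(filterB);
  int L = seq.size();
  if (L < k) return IntegerVector(0);
  int W = L - k + 1;
  int best_b = -1, best_len = 0, run = 0;
  for (int o = 0; o < W; o++) {
    run = window_in_B(seq, o, k, B) ? run + 1 : 0;
    if (run > best_len) { best_len = run; best_b = o - run + 1; }
  }
  if (best_len == 0) return IntegerVector(0);
  return IntegerVector::create(best_b + 1, best_b + best_len);  // 1-based
}

// Whole-dataset pass 3; sequential but order-independent by construction.
// [[Rcpp::export(name = ".pass3_cpp")]]
List pass3_cpp(CharacterVector seqs, SEXP quals, int k, SEXP filterB,
               int cutoff, int phred_offset, double limit) {
  KmerSet* B = get_set(filterB);
  bool has_q = quals != R_NilValue;
  CharacterVector qv;
  if (has_q) qv = as<CharacterVector>(quals);
  int n = seqs.size();
  CharacterVector out(n);
  LogicalVector anchored(n), budget_stop(n);
  std::vector<int> e_read, e_pos, a_read, a_pos;
  std::vector<char> e_from, e_to;
  std::vector<double> e_w;
  for (int i = 0; i < n; i++) {
    std::string s(CHAR(seqs[i]), LENGTH(seqs[i]));
    std::string q;
    if (has_q && qv[i] != NA_STRING) {
      q.assign(CHAR(qv[i]), LENGTH(qv[i]));
      if (q.size() != s.size()) stop("read %d: quality/sequence length mismatch", i + 1);
    }
    CorrectScratch sc;
    correct_one(s, q, k, B, cutoff, phred_offset, limit, sc);
    out[i] = s;
    anchored[i] = sc.anchored;
    budget_stop[i] = sc.budget_stop;
    for (const EditRec& e : sc.edits) {
      e_read.push_back(i + 1);
      e_pos.push_back(e.pos + 1);
      e_from.push_back(e.from);
      e_to.push_back(e.to);
      e_w.push_back(e.w);
    }
    for (int p : sc.ambig) { a_read.push_back(i + 1); a_pos.push_back(p + 1); }
  }
  int ne = e_read.size(), na = a_read.size();
  IntegerVector er(ne), ep(ne), ar(na), ap(na);
  CharacterVector ef(ne), et(ne);
  NumericVector ew(ne);
  for (int i = 0; i < ne; i++) {
    er[i] = e_read[i]; ep[i] = e_pos[i];
    ef[i] = std::string(1, e_from[i]); et[i] = std::string(1, e_to[i]);
    ew[i] = e_w[i];
  }
  for (int i = 0; i < na; i++) { ar[i] = a_read[i]; ap[i] = a_pos[i]; }
  return List::create(
      _["seq"] = out, _["anchored"] = anchored, _["budget_stop"] = budget_stop,
      _["edit_read"] = er, _["edit_pos"] = ep, _["edit_from"] = ef,
      _["edit_to"] = et, _["edit_weight"] = ew, _["ambig_read"] = ar,
      _["ambig_pos"] = ap);
}
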