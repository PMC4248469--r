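#include "core.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".rc_cpp")]]
CharacterVector rc_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    std::string r(L, 0);
    for (int j = 0; j < L; j++) {
      char c = iupac_comp(s[L - 1 - j]);
      if (!c)
        stop("malformed sequence: non-IUPAC character '%c' in element %d",
             s[L - 1 - j], i + 1);
      r[j] = c;
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export(name = ".canonicalize_cpp")]]
CharacterVector canonicalize_cpp(CharacterVector words) {
  int n = words.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    const char* w = CHAR(words[i]);
    int k = LENGTH(words[i]);
    if (k < 1 || k > 31)
      stop("k-mer length must be in [1, 31], got %d (element %d)", k, i + 1);
    uint64_t f;
    if (!encode_word(w, k, f))
      stop("ambiguous base in k-mer '%s': canonicalization requires A/C/G/T only",
           w);
    uint64_t r = rc_word_code(f, k);
    out[i] = decode_word(f < r ? f : r, k);
  }
  return out;
}

// [[Rcpp::export(name = ".encode2bit_cpp")]]
NumericVector encode2bit_cpp(CharacterVector words) {
  int n = words.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    const char* w = CHAR(words[i]);
    int k = LENGTH(words[i]);
    if (k < 1 || k > 26)
      stop("encode2bit: k must be in [1, 26] so the code is exact in a double");
    uint64_t c;
    if (!encode_word(w, k, c)) stop("encode2bit: non-ACGT character in '%s'", w);
    out[i] = (double)c;
  }
  return out;
}

// [[Rcpp::export(name = ".decode2bit_cpp")]]
CharacterVector decode2bit_cpp(NumericVector codes, int k) {
  if (k < 1 || k > 26)
    stop("decode2bit: k must be in [1, 26] so the code is exact in a double");
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    double d = codes[i];
    if (d < 0 || d != std::floor(d)) stop("decode2bit: codes must be nonnegative integers");
    out[i] = decode_word((uint64_t)d, k);
  }
  return out;
}

// [[Rcpp::export(name = ".kmer_windows_cpp")]]
List kmer_windows_cpp(std::string seq, int k) {
  int L = seq.size();
  int W = (L >= k) ? (L - k + 1) : 0;
  CharacterVector word(W);
  LogicalVector valid(W);
  for (int o = 0; o < W; o++) {
    word[o] = seq.substr(o, k);
    bool ok = true;
    for (int j = 0; j < k; j++)
      if (base_code(seq[o + j]) < 0) { ok = false; break; }
    valid[o] = ok;
  }
  return List::create(_["word"] = word, _["valid"] = valid);
}
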