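#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Canonical k-mer spectrum: k-mers are counted as the lexicographic minimum of
// the 2-bit encoding of the forward k-mer and its reverse complement (the
// encoding is order-isomorphic to the string order over A<C<G<T). Windows
// containing ambiguous residues are skipped. k <= 32 so a k-mer fits one
// 64-bit word.
// [[Rcpp::export]]
DataFrame kmer_spectrum_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, uint32_t> tbl;
  const int shift = 2 * (k - 1);
  const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP sr = STRING_ELT(reads, r);
    if (sr == NA_STRING) continue;
    const char* s = CHAR(sr);
    const int n = LENGTH(sr);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | uint64_t(c)) & mask;
      rev = (rev >> 2) | (uint64_t(3 - c) << shift);
      if (++run >= k) ++tbl[fwd < rev ? fwd : rev];
    }
  }
  std::unordered_map<uint32_t, double> hist;
  for (const auto& kv : tbl) hist[kv.second] += 1.0;
  std::vector<std::pair<uint32_t, double> > out(hist.begin(), hist.end());
  std::sort(out.begin(), out.end());
  const int m = static_cast<int>(out.size());
  IntegerVector freq(m);
  NumericVector cnt(m);
  for (int i = 0; i < m; ++i) {
    freq[i] = static_cast<int>(out[i].first);
    cnt[i] = out[i].second;
  }
  return DataFrame::create(_["frequency"] = freq, _["n_kmers"] = cnt);
}
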