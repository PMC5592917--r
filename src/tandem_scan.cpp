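#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Tandem-repeat scanner on the lag-u self-comparison.
//
// For a fixed unit length u, position j (0-based) is compared with position
// j - u: +match if equal, +mismatch otherwise. A candidate locus [s, e)
// (sequence coordinates, half-open) has score = sum over comparison positions
// j in [s+u, e); a perfect repeat of total length l scores l - u. Candidates
// must span at least two units (e - s >= 2u) and reach min_score.
//
// The reported locus set is defined greedily: repeatedly accept the
// highest-scoring candidate over all units that does not overlap an already
// accepted locus, ties broken toward the smaller unit, then the smaller
// start, then the smaller end. Implemented with per-unit segment lists
// (regions not yet blocked by accepted loci or ambiguous residues) and a
// min-length-constrained maximum-subarray search per segment.

struct Cand {
  bool valid;
  long long score;
  int start, end;  // sequence coords, half-open
  Cand() : valid(false), score(0), start(-1), end(-1) {}
};

struct Seg {
  int A, B;  // half-open sequence interval, ambiguity-free
  bool dirty;
  Cand best;
  Seg(int a, int b) : A(a), B(b), dirty(true), best() {}
};

static Cand seg_best(const std::string& s, int u, int A, int B,
                     int match, int mismatch) {
  Cand best;
  const int lo = A + u;   // first possible comparison position
  const int hi = B - 1;   // last possible comparison position
  if (hi - lo + 1 < u) return best;  // cannot fit two units
  const int m = hi - lo + 1;
  std::vector<long long> pref(m + 1, 0);  // pref[t] = sum y[lo .. lo+t-1]
  for (int t = 0; t < m; ++t) {
    const int j = lo + t;
    pref[t + 1] = pref[t] + ((s[j] == s[j - u]) ? match : mismatch);
  }
  bool have = false;
  long long bmin = 0;
  int bmin_j1 = lo;
  // interval = comparisons [j1, j2], j2 - j1 >= u - 1; locus [j1-u, j2+1)
  for (int j2 = lo + u - 1; j2 <= hi; ++j2) {
    const int j1_new = j2 - u + 1;
    const long long p = pref[j1_new - lo];  // prefix before j1_new
    if (!have || p < bmin) { bmin = p; bmin_j1 = j1_new; have = true; }
    const long long sc = pref[j2 - lo + 1] - bmin;
    const int st = bmin_j1 - u, en = j2 + 1;
    if (!best.valid || sc > best.score ||
        (sc == best.score &&
         (st < best.start || (st == best.start && en < best.end)))) {
      best.valid = true;
      best.score = sc;
      best.start = st;
      best.end = en;
    }
  }
  return best;
}

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' ||
         c == 'a' || c == 'c' || c == 'g' || c == 't';
}

// [[Rcpp::export]]
DataFrame tandem_scan_cpp(std::string seq, IntegerVector units,
                          int match, int mismatch, int min_score) {
  const int n = static_cast<int>(seq.size());
  const int nu = static_cast<int>(units.size());

  // initial segments: maximal ambiguity-free runs
  std::vector<std::pair<int, int> > runs;
  int i = 0;
  while (i < n) {
    if (!is_base(seq[i])) { ++i; continue; }
    int j = i;
    while (j < n && is_base(seq[j])) ++j;
    runs.push_back(std::make_pair(i, j));
    i = j;
  }

  std::vector<std::vector<Seg> > segs(nu);
  for (int ui = 0; ui < nu; ++ui)
    for (size_t r = 0; r < runs.size(); ++r)
      segs[ui].push_back(Seg(runs[r].first, runs[r].second));

  std::vector<int> out_start, out_end, out_unit, out_mm;
  std::vector<double> out_score;

  for (;;) {
    bool found = false;
    long long b_score = 0;
    int b_unit = 0, b_start = 0, b_end = 0;
    for (int ui = 0; ui < nu; ++ui) {
      const int u = units[ui];
      for (size_t si = 0; si < segs[ui].size(); ++si) {
        Seg& sg = segs[ui][si];
        if (sg.dirty) {
          sg.best = seg_best(seq, u, sg.A, sg.B, match, mismatch);
          sg.dirty = false;
        }
        if (!sg.best.valid || sg.best.score < min_score) continue;
        const Cand& c = sg.best;
        if (!found || c.score > b_score ||
            (c.score == b_score &&
             (u < b_unit ||
              (u == b_unit &&
               (c.start < b_start ||
                (c.start == b_start && c.end < b_end)))))) {
          found = true;
          b_score = c.score;
          b_unit = u;
          b_start = c.start;
          b_end = c.end;
        }
      }
    }
    if (!found) break;

    int mm = 0;
    for (int j = b_start + b_unit; j < b_end; ++j)
      if (seq[j] != seq[j - b_unit]) ++mm;
    out_start.push_back(b_start);
    out_end.push_back(b_end);
    out_unit.push_back(b_unit);
    out_score.push_back(static_cast<double>(b_score));
    out_mm.push_back(mm);

    // block [b_start, b_end) for every unit
    for (int ui = 0; ui < nu; ++ui) {
      std::vector<Seg> next;
      next.reserve(segs[ui].size() + 1);
      for (size_t si = 0; si < segs[ui].size(); ++si) {
        const Seg& sg = segs[ui][si];
        if (sg.B <= b_start || sg.A >= b_end) {
          next.push_back(sg);
        } else {
          if (b_start > sg.A) next.push_back(Seg(sg.A, b_start));
          if (sg.B > b_end) next.push_back(Seg(b_end, sg.B));
        }
      }
      segs[ui].swap(next);
    }
  }

  return DataFrame::create(
      _["start"] = wrap(out_start), _["end"] = wrap(out_end),
      _["unit_length"] = wrap(out_unit), _["score"] = wrap(out_score),
      _["n_mismatches"] = wrap(out_mm));
}
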