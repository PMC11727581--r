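#include <Rcpp.h>
#include <cstdlib>
using namespace Rcpp;

// Banded ungapped scan for the best target-site-duplication pair between a
// left and a right flank.  Enumerates every diagonal (a = left start,
// b = right start) and extends along it, accumulating mismatches; abandons a
// diagonal once the mismatch budget is exceeded (mismatch count is monotone
// in the extension length, so no longer alignment on that diagonal can
// qualify).  Score is unit-per-base: matches - mismatches.
//
// Constraints:
//   * aligned length >= min_len
//   * mismatches <= max_mis
//   * left-copy end   e = a + len   in [left_end_lo, left_end_hi]
//   * right-copy start b            in [right_start_lo, right_start_hi]
//   * e - b <= max_end_start_diff   (keeps the two copies non-overlapping in
//     reference coordinates when the flanks themselves overlap)
//
// Tie-breaking, in order: higher score, longer length, fewer mismatches,
// smaller |e - left_edge| (distance of the left copy end to the fill edge;
// skipped when left_edge < 0), smaller left start, smaller right start.
//
// Returns an empty vector when no qualifying pair exists, otherwise
// c(left_start, left_end, right_start, right_end, length, matches,
//   mismatches, score), all 0-based, ends exclusive.
// [[Rcpp::export]]
IntegerVector tsd_scan_cpp(std::string left, std::string right,
                           int min_len, int max_mis,
                           int left_end_lo, int left_end_hi,
                           int right_start_lo, int right_start_hi,
                           int left_edge, int max_end_start_diff) {
  const int n = (int)left.size(), m = (int)right.size();
  bool found = false;
  int bs = 0, blen = 0, bmm = 0, bls = 0, ble = 0, brs = 0, bdist = 0;

  const int b_lo = std::max(0, right_start_lo);
  const int b_hi = std::min(m - min_len, right_start_hi);

  for (int a = 0; a + min_len <= n; ++a) {
    for (int b = b_lo; b <= b_hi; ++b) {
      int mm = 0;
      const int kmax = std::min(n - a, m - b);
      for (int k = 0; k < kmax; ++k) {
        if (left[a + k] != right[b + k]) {
          if (++mm > max_mis) break;
        }
        const int len = k + 1;
        if (len < min_len) continue;
        const int e = a + len;
        if (e < left_end_lo || e > left_end_hi) continue;
        if (e - b > max_end_start_diff) continue;
        const int sc = len - 2 * mm;
        const int dist = (left_edge >= 0) ? std::abs(e - left_edge) : 0;
        bool better;
        if (!found)            better = true;
        else if (sc != bs)     better = sc > bs;
        else if (len != blen)  better = len > blen;
        else if (mm != bmm)    better = mm < bmm;
        else if (dist != bdist) better = dist < bdist;
        else if (a != bls)     better = a < bls;
        else                   better = b < brs;
        if (better) {
          found = true;
          bs = sc; blen = len; bmm = mm; bls = a; ble = e; brs = b;
          bdist = dist;
        }
      }
    }
  }
  if (!found) return IntegerVector(0);
  return IntegerVector::create(bls, ble, brs, brs + blen, blen,
                               blen - bmm, bmm, bs);
}
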