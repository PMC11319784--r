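#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost edit distance (insert/delete/substitute), two-row DP.
static int edit_distance(const std::string& a, const std::string& b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
int cpp_levenshtein(const std::string& a, const std::string& b) {
  return edit_distance(a, b);
}

// Compare similarities 100*(m-d)/m exactly: (m1-d1)/m1 > (m2-d2)/m2.
static bool sim_greater(int d1, int m1, int d2, int m2) {
  return (long long)(m1 - d1) * m2 > (long long)(m2 - d2) * m1;
}

// Best fuzzy occurrence of `query` among substrings of `note` starting at or
// after `from` (0-based) and ending at or before `hi` (0-based inclusive;
// hi < 0 means end of note).  Candidate lengths range over
// [ceil(0.8*|q|), floor(1.2*|q|) + 1]: a similarity >= 90 bounds the length
// difference by 10% of the longer string, so the window is sound with margin.
// Similarity = 100 * (1 - d / max(|q|, |c|)); a candidate qualifies when
// 100*(max - d) >= threshold*max, compared rationally so threshold boundaries
// (e.g. exactly 90) are not lost to floating point.
//
// leftmost mode (rightmost = false): maximise similarity; ties -> smaller
// start, then shorter candidate.  rightmost mode: among qualifying candidates
// maximise the end offset; ties -> higher similarity, then first found.
// Returns c(start, end, score) 0-based inclusive, or an empty vector.
// [[Rcpp::export]]
NumericVector cpp_fuzzy_best(const std::string& note, const std::string& query,
                             int from, int hi, double threshold,
                             bool rightmost) {
  const int n = (int)note.size(), m = (int)query.size();
  if (m == 0 || n == 0) return NumericVector(0);
  const int hi_idx = (hi < 0 || hi > n - 1) ? n - 1 : hi;
  if (from < 0) from = 0;
  const int min_len = std::max(1, (int)std::ceil(0.8 * m));
  const int max_len = (int)std::floor(1.2 * m) + 1;

  int best_d = 0, best_max = 0, best_s = -1, best_len = 0;
  std::vector<int> prev(max_len + 1), cur(max_len + 1);

  for (int s = from; s <= hi_idx; ++s) {
    const int limit = std::min(max_len, hi_idx - s + 1);
    if (limit < min_len) continue;
    // One DP pass per start: final row holds d(query, note[s, s+L-1]) for
    // every candidate length L <= limit.
    for (int j = 0; j <= limit; ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
      cur[0] = i;
      const char qc = query[i - 1];
      for (int j = 1; j <= limit; ++j) {
        int sub = prev[j - 1] + (qc == note[s + j - 1] ? 0 : 1);
        cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
      }
      std::swap(prev, cur);
    }
    for (int L = min_len; L <= limit; ++L) {
      const int d = prev[L];
      const int mx = std::max(m, L);
      if (100.0 * (mx - d) + 1e-9 < threshold * mx) continue;
      bool take = false;
      if (best_s < 0) {
        take = true;
      } else if (!rightmost) {
        // scan order is ascending start then ascending length, so replacing
        // only on a strictly better similarity implements the tie-breaks.
        take = sim_greater(d, mx, best_d, best_max);
      } else {
        const int end = s + L - 1, best_end = best_s + best_len - 1;
        take = (end > best_end) ||
               (end == best_end && sim_greater(d, mx, best_d, best_max));
      }
      if (take) {
        best_d = d;
        best_max = mx;
        best_s = s;
        best_len = L;
      }
    }
  }
  if (best_s < 0) return NumericVector(0);
  double score = 100.0 * (double)(best_max - best_d) / (double)best_max;
  return NumericVector::create(best_s, best_s + best_len - 1, score);
}
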