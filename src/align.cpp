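#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Scoring: +1 for an identical A/C/G/T pair, -1 otherwise (ambiguity codes
// and N never match), -2 per gap position; terminal gaps are free
// (overlap / free-end-gap global alignment).
static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline int sub_score(char a, char b) {
  return (a == b && is_acgt(a)) ? 1 : -1;
}

static const int GAP = 2; // penalty per gap position (subtracted)

// Free-end-gap global alignment of a and b.
// Among all score-optimal alignments the maximum attainable number of
// identical aligned A/C/G/T pairs is computed with a second DP layer, so
// the identity value does not depend on traceback tie-breaking.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  std::vector<int> H((m + 1) * (n + 1)); // best score
  std::vector<int> M((m + 1) * (n + 1)); // max matches among optimal
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) { H[at(0, j)] = 0; M[at(0, j)] = 0; }
  for (int i = 0; i <= m; ++i) { H[at(i, 0)] = 0; M[at(i, 0)] = 0; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int s = sub_score(a[i - 1], b[j - 1]);
      const int mm = (s > 0) ? 1 : 0;
      int hd = H[at(i - 1, j - 1)] + s;
      int hu = H[at(i - 1, j)] - GAP;
      int hl = H[at(i, j - 1)] - GAP;
      int h = std::max(hd, std::max(hu, hl));
      int best_m = -1;
      if (hd == h) best_m = std::max(best_m, M[at(i - 1, j - 1)] + mm);
      if (hu == h) best_m = std::max(best_m, M[at(i - 1, j)]);
      if (hl == h) best_m = std::max(best_m, M[at(i, j - 1)]);
      H[at(i, j)] = h;
      M[at(i, j)] = best_m;
    }
  }

  // Free end gaps: best cell on last row or last column; ties prefer more
  // matches, then larger i + j, then larger i (deterministic).
  int bi = m, bj = n, bs = H[at(m, n)], bm = M[at(m, n)];
  auto consider = [&](int i, int j) {
    int h = H[at(i, j)], mm = M[at(i, j)];
    if (h > bs || (h == bs && (mm > bm ||
        (mm == bm && (i + j > bi + bj || (i + j == bi + bj && i > bi)))))) {
      bs = h; bm = mm; bi = i; bj = j;
    }
  };
  for (int i = 0; i <= m; ++i) consider(i, n);
  for (int j = 0; j <= n; ++j) consider(m, j);

  // Traceback (diag > up > left among moves that preserve score AND the
  // max-match count, so the emitted alignment realizes bm matches).
  std::string ra, rb;
  for (int i = m; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = n; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const int s = sub_score(a[i - 1], b[j - 1]);
    const int mm = (s > 0) ? 1 : 0;
    const int h = H[at(i, j)], mk = M[at(i, j)];
    if (H[at(i - 1, j - 1)] + s == h && M[at(i - 1, j - 1)] + mm == mk) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (H[at(i - 1, j)] - GAP == h && M[at(i - 1, j)] == mk) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = bs, _["matches"] = bm,
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// Exhaustive search over contiguous column intervals [s, e) of an alignment.
// A row covers an interval iff it is non-gap at both interval ends and its
// internal gap fraction is <= max_gap_frac. Among intervals with coverage
// >= min_cover rows, returns the longest; ties by higher coverage, then
// leftmost start. Returns integer(0)-style empty result if none qualifies.
// gap: logical matrix rows x cols, TRUE where the row has a gap.
// [[Rcpp::export(name = ".window_search_cpp")]]
List window_search_cpp(LogicalMatrix gap, int min_cover, double max_gap_frac) {
  const int R = gap.nrow(), C = gap.ncol();
  if (R == 0 || C == 0) stop("empty alignment");
  // prefix gap counts per row
  std::vector<std::vector<int>> pg(R, std::vector<int>(C + 1, 0));
  for (int r = 0; r < R; ++r)
    for (int c = 0; c < C; ++c)
      pg[r][c + 1] = pg[r][c] + (gap(r, c) ? 1 : 0);

  int best_len = -1, best_cov = -1, best_s = -1, best_e = -1;
  for (int s = 0; s < C; ++s) {
    for (int e = s + 1; e <= C; ++e) {
      const int len = e - s;
      int cov = 0;
      for (int r = 0; r < R; ++r) {
        if (gap(r, s) || gap(r, e - 1)) continue;
        const int g = pg[r][e] - pg[r][s];
        if (g <= max_gap_frac * len) ++cov;
      }
      if (cov < min_cover) continue;
      if (len > best_len || (len == best_len && cov > best_cov)) {
        best_len = len; best_cov = cov; best_s = s; best_e = e;
      }
    }
  }
  if (best_len < 0)
    return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["start"] = best_s,
                      _["end"] = best_e, _["coverage"] = best_cov);
}
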