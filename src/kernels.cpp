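#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// A gap of length k costs gap_open + k * gap_ext (both negative).
// Deterministic: the best cell is the first (smallest query index, then
// smallest subject index) cell attaining the maximal score; traceback
// prefers diagonal moves, then gaps in the subject, then gaps in the query.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, -1e18));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, -1e18));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] + gap_open + gap_ext, E[i][j - 1] + gap_ext);
      F[i][j] = std::max(H[i - 1][j] + gap_open + gap_ext, F[i - 1][j] + gap_ext);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = H[i - 1][j - 1] + s;
      h = std::max(h, E[i][j]);
      h = std::max(h, F[i][j]);
      h = std::max(h, 0.0);
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["matches"] = 0,
                        _["aligned_len"] = 0, _["gaps"] = 0,
                        _["qaln"] = "", _["saln"] = "");
  }
  // traceback
  std::string qa, sa;
  int i = bi, j = bj;
  int matches = 0, gaps = 0;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      if (H[i][j] == 0.0) break;
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (H[i][j] == H[i - 1][j - 1] + s) {
        qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) matches++;
        --i; --j;
      } else if (H[i][j] == F[i][j]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') { // gap in subject, consume a
      qa.push_back(a[i - 1]); sa.push_back('-'); gaps++;
      if (F[i][j] == H[i - 1][j] + gap_open + gap_ext) { --i; state = 'H'; }
      else { --i; }
    } else { // E: gap in query, consume b
      qa.push_back('-'); sa.push_back(b[j - 1]); gaps++;
      if (E[i][j] == H[i][j - 1] + gap_open + gap_ext) { --j; state = 'H'; }
      else { --j; }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best,
                      _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["matches"] = matches,
                      _["aligned_len"] = (int) qa.size(),
                      _["gaps"] = gaps,
                      _["qaln"] = qa, _["saln"] = sa);
}

static inline bool can_pair(char x, char y) {
  return (x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'T') || (x == 'T' && y == 'G');
}

// Nussinov-style maximum base pairing with minimum loop length
// (j - i > min_loop for every pair) and a minimum helix length: every
// helix must consist of at least `min_helix` contiguous stacked pairs
// (min_helix = 1 is the classic Nussinov recursion; min_helix = 2
// disallows isolated pairs). Decomposition: M[i][j] = max(M[i][j-1],
// max_k M[i][k-1] + HX(k, j)) where HX(k, j) is the best score with a
// helix of length h >= min_helix closing (k, j). Traceback places the
// longest optimal helix first (extend the current helix before opening a
// new one), giving a deterministic structure.
// [[Rcpp::export]]
IntegerVector nussinov_cpp(std::string s, int min_loop = 3,
                           int min_helix = 1) {
  int n = s.size();
  IntegerVector partner(n, -1);
  if (n == 0) return partner;
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  // hx(k, j): best score of a structure on [k, j] whose outermost pair is
  // (k, j) closed by a helix of length >= min_helix; also records best h.
  auto hx = [&](int k, int j, int &best_h) {
    int best = -1; best_h = 0;
    int h = 0;
    while (true) {
      int a = k + h, b = j - h;
      if (b - a <= min_loop || !can_pair(s[a], s[b])) break;
      ++h;
      if (h >= min_helix) {
        int inner = (k + h <= j - h) ? M[k + h][j - h] : 0;
        int v = h + inner;
        if (v > best || (v == best && h > best_h)) { best = v; best_h = h; }
      }
    }
    return best;
  };
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int h;
        int v = hx(k, j, h);
        if (v >= 0) {
          int left = (k > i) ? M[i][k - 1] : 0;
          if (left + v > best) best = left + v;
        }
      }
      M[i][j] = best;
    }
  }
  std::vector<std::pair<int,int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || M[i][j] == 0) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      int h;
      int v = hx(k, j, h);
      if (v < 0) continue;
      int left = (k > i) ? M[i][k - 1] : 0;
      if (left + v == M[i][j]) {
        for (int t = 0; t < h; ++t) {
          partner[k + t] = j - t;
          partner[j - t] = k + t;
        }
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + h < j - h) stack.push_back(std::make_pair(k + h, j - h));
        done = true;
      }
    }
  }
  return partner;
}

// Exhaustive search for the best duplicated substring pair between two
// windows (used for target site duplication detection). Returns the longest
// pair with Hamming mismatch fraction <= max_mm_frac; ties broken by fewer
// mismatches, then by the copy in `a` ending closest to the end of `a`
// (the insertion boundary), then by the smallest start in `b`.
// Returns c(astart, bstart, len, mismatches), all 0-based; len 0 if none.
// [[Rcpp::export]]
IntegerVector tsd_search_cpp(std::string a, std::string b,
                             int min_len, int max_len, double max_mm_frac) {
  int na = a.size(), nb = b.size();
  int top = std::min(max_len, std::min(na, nb));
  for (int L = top; L >= min_len; --L) {
    int allow = (int)(max_mm_frac * L);
    int best_mm = allow + 1, best_as = -1, best_bs = -1;
    for (int as = na - L; as >= 0; --as) {      // a-end closest to boundary first
      for (int bs = 0; bs + L <= nb; ++bs) {
        int mm = 0;
        for (int k = 0; k < L && mm < best_mm; ++k)
          if (a[as + k] != b[bs + k]) ++mm;
        if (mm < best_mm) { best_mm = mm; best_as = as; best_bs = bs; }
      }
    }
    if (best_as >= 0) {
      return IntegerVector::create(best_as, best_bs, L, best_mm);
    }
  }
  return IntegerVector::create(-1, -1, 0, 0);
}
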