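#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Strings arrive as integer code-point vectors (utf8ToInt on the R side),
// so offsets count Unicode code points, never bytes.

// [[Rcpp::export]]
int lev_distance_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static inline bool is_space_cp(int cp) {
  return cp == 0x20 || cp == 0x09 || cp == 0x0A || cp == 0x0D ||
         cp == 0x0B || cp == 0x0C || cp == 0xA0;
}

// Sliding-window scan: at each text offset i one DP table of the token
// against text[i, i + wmax) yields, in its last row, the distance to every
// window width at once; widths in [wmin, wmax] are tested against theta.
// With whitespace_barrier, candidate windows never span whitespace (PHI
// tokens contain none, so such windows cannot be token occurrences).
// Returns 0-based half-open spans.
// [[Rcpp::export]]
List scan_token_cpp(IntegerVector text, IntegerVector token,
                    double theta, int wmin, int wmax,
                    bool whitespace_barrier) {
  int n = text.size(), L = token.size();
  std::vector<int> starts, ends;
  std::vector<double> sims;
  if (L > 0 && n > 0 && wmin <= wmax) {
    if (wmin < 1) wmin = 1;
    // run_end[i]: first offset >= i holding whitespace (or n)
    std::vector<int> run_end(n + 1, n);
    if (whitespace_barrier) {
      for (int i = n - 1; i >= 0; --i) {
        run_end[i] = is_space_cp(text[i]) ? i : run_end[i + 1];
      }
    }
    std::vector<int> prev(wmax + 1), cur(wmax + 1);
    for (int i = 0; i < n; ++i) {
      int maxw = std::min(wmax, n - i);
      if (whitespace_barrier) maxw = std::min(maxw, run_end[i] - i);
      if (maxw < wmin) continue;
      for (int j = 0; j <= maxw; ++j) prev[j] = j;
      for (int r = 1; r <= L; ++r) {
        cur[0] = r;
        for (int j = 1; j <= maxw; ++j) {
          int cost = (token[r - 1] == text[i + j - 1]) ? 0 : 1;
          cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                            prev[j - 1] + cost);
        }
        std::swap(prev, cur);
      }
      // prev[w] == lev(token, text[i, i + w))
      for (int w = wmin; w <= maxw; ++w) {
        int mx = std::max(L, w);
        double sim = 1.0 - static_cast<double>(prev[w]) / mx;
        if (sim >= theta) {
          starts.push_back(i);
          ends.push_back(i + w);
          sims.push_back(sim);
        }
      }
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["end"] = wrap(ends),
                      _["similarity"] = wrap(sims));
}
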