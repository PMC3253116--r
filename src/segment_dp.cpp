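#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal least-squares change-point segmentation by dynamic programming.
//
// For every k = 1..max_k, finds the partition of x into k contiguous
// segments (each of length >= min_len for k >= 2; a single segment is
// always admissible) minimizing the residual sum of squares about the
// segment means. Exact, not greedy: dp[k][j] = min_i dp[k-1][i-1] +
// cost(i, j), with cost from prefix sums. Ties broken toward the
// leftmost boundary (strict improvement required to move right).
//
// Returns rss[k] and the 1-based segment start indices for each k.
// [[Rcpp::export]]
List segment_dp_cpp(NumericVector x, int max_k, int min_len) {
  const int n = x.size();
  if (n < 1) stop("empty signal");
  if (min_len < 1) min_len = 1;
  std::vector<double> s(n + 1, 0.0), ss(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    ss[i + 1] = ss[i] + x[i] * x[i];
  }
  int K = std::min(max_k, n / min_len);
  if (K < 1) K = 1;

  std::vector<double> prev(n), cur(n);
  std::vector<int> back((size_t)K * n, -1);
  std::vector<double> rss_k(K);
  std::vector<std::vector<int>> backs;  // per-k copies for backtracking

  const double* sp = s.data();
  const double* ssp = ss.data();
  for (int j = 0; j < n; ++j) {
    const double su = sp[j + 1];
    prev[j] = ssp[j + 1] - su * su / (j + 1);
    if (prev[j] < 0) prev[j] = 0;
    back[j] = 0;
  }
  rss_k[0] = prev[n - 1];

  for (int k = 1; k < K; ++k) {
    int* bk = back.data() + (size_t)k * n;
    std::fill(cur.begin(), cur.end(), R_PosInf);
    const int jlo = (k + 1) * min_len - 1;
    for (int j = jlo; j < n; ++j) {
      const double sj = sp[j + 1], ssj = ssp[j + 1];
      double best = R_PosInf;
      int bi = -1;
      const int ilo = k * min_len;
      const int ihi = j - min_len + 1;
      for (int i = ilo; i <= ihi; ++i) {
        const double p = prev[i - 1];
        if (p >= best) continue;
        const double su = sj - sp[i];
        double c = ssj - ssp[i] - su * su / (j - i + 1);
        if (c < 0) c = 0;
        const double v = p + c;
        if (v < best) { best = v; bi = i; }
      }
      cur[j] = best;
      bk[j] = bi;
    }
    rss_k[k] = cur[n - 1];
    std::swap(prev, cur);
  }

  NumericVector rss(K);
  List starts(K);
  for (int k = 0; k < K; ++k) {
    rss[k] = rss_k[k];
    IntegerVector st(k + 1);
    int j = n - 1;
    for (int kk = k; kk >= 0; --kk) {
      const int i = back[(size_t)kk * n + j];
      st[kk] = i + 1;  // 1-based
      j = i - 1;
    }
    starts[k] = st;
  }
  return List::create(_["rss"] = rss, _["starts"] = starts);
}
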