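// Circular binary segmentation (Olshen-Venkatraman recursion).
//
// At each stage the pair of circular split points (i, j) maximizing the
// t-like contrast between the arc (i, j] and its complement is located by
// exhaustive O(m^2) scan; the split is accepted if its permutation p-value
// (within-segment shuffles, R's RNG) is below alpha, and the recursion
// continues in the resulting subsegments. No pruning/undo step is applied;
// downstream merging of equal-copy-number segments recalibrates
// over-segmentation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// max over (i, j) of |mean(arc) - mean(rest)| / sqrt(1/k + 1/(m-k)); the
// pooled-variance scale is constant across split points and permutations, so
// it cancels from the permutation test and is omitted.
static double max_circ_stat(const std::vector<double>& x, int& bi, int& bj) {
  const int m = (int)x.size();
  std::vector<double> S(m + 1, 0.0);
  for (int i = 0; i < m; ++i) S[i + 1] = S[i] + x[i];
  const double tot = S[m];
  double best = 0.0;
  bi = -1; bj = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j <= m; ++j) {
      int k = j - i;
      if (k == m) continue;
      double arc = S[j] - S[i];
      double d = arc / k - (tot - arc) / (m - k);
      double t = std::fabs(d) / std::sqrt(1.0 / k + 1.0 / (m - k));
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
  return best;
}

static void segment_rec(std::vector<double> x, int offset, double alpha,
                        int nperm, std::vector<int>& bps) {
  const int m = (int)x.size();
  if (m < 2) return;
  int bi, bj;
  double obs = max_circ_stat(x, bi, bj);
  if (!(obs > 0.0)) return;  // constant segment
  int exceed = 0, tossed = 0;
  std::vector<double> p = x;
  for (int r = 0; r < nperm; ++r) {
    for (int i = m - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    int di, dj;
    if (max_circ_stat(p, di, dj) >= obs) {
      ++exceed;
      // sequential early-out: once the p-value cannot fall below alpha,
      // further permutations cannot change the decision
      if ((1.0 + exceed) / (nperm + 1.0) >= alpha) { tossed = 1; break; }
    }
  }
  double pval = (1.0 + exceed) / (nperm + 1.0);
  if (tossed || pval >= alpha) return;
  // accepted: breakpoints at arc ends (interior only)
  std::vector<int> cuts;
  if (bi > 0) cuts.push_back(bi);
  if (bj < m) cuts.push_back(bj);
  for (int c : cuts) bps.push_back(offset + c);
  // recurse into the pieces delimited by the accepted cuts
  std::vector<int> edges;
  edges.push_back(0);
  for (int c : cuts) edges.push_back(c);
  edges.push_back(m);
  for (size_t e = 0; e + 1 < edges.size(); ++e) {
    int a = edges[e], b = edges[e + 1];
    if (b - a >= 2) {
      std::vector<double> sub(x.begin() + a, x.begin() + b);
      segment_rec(std::move(sub), offset + a, alpha, nperm, bps);
    }
  }
}

// [[Rcpp::export(name = ".cbs_segment_cpp")]]
Rcpp::IntegerVector cbs_segment_cpp(Rcpp::NumericVector x, double alpha,
                                    int nperm) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> bps;
  segment_rec(std::move(v), 0, alpha, nperm, bps);  // RNGScope via attributes
  std::sort(bps.begin(), bps.end());
  return Rcpp::IntegerVector(bps.begin(), bps.end());
}

// [[Rcpp::export(name = ".cbs_max_stat_cpp")]]
Rcpp::List cbs_max_stat_cpp(Rcpp::NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  int bi, bj;
  double s = max_circ_stat(v, bi, bj);
  return Rcpp::List::create(Rcpp::Named("stat") = s,
                            Rcpp::Named("i") = bi, Rcpp::Named("j") = bj);
}
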