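#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Classic dynamic time warping: local cost |a_i - b_j|, symmetric step
// pattern (match / insert / delete), boundary-anchored, no window
// constraint.  Returns the optimal cumulative path cost.

namespace {

double dtw_core(const double *a, int n, const double *b, int m) {
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double c = std::abs(a[0] - b[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      double best = prev[j];                       // insertion
      if (j > 0) {
        best = std::min(best, cur[j - 1]);         // deletion
        best = std::min(best, prev[j - 1]);        // match
      }
      cur[j] = best + c;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

} // namespace

// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericVector a, NumericVector b) {
  return dtw_core(a.begin(), a.size(), b.begin(), b.size());
}

// Pairwise event distances: each element of `series` is a days x variables
// matrix (same column set across events; row counts may differ).  The
// distance between two events is the equal-weight sum over variables of the
// univariate DTW distances between the corresponding columns.
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List series, NumericVector weights) {
  int n = series.size();
  int nv = weights.size();
  std::vector<NumericMatrix> mats(n);
  for (int i = 0; i < n; ++i) mats[i] = as<NumericMatrix>(series[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int v = 0; v < nv; ++v) {
        s += weights[v] * dtw_core(&mats[i](0, v), mats[i].nrow(),
                                   &mats[j](0, v), mats[j].nrow());
      }
      d(i, j) = s;
      d(j, i) = s;
    }
  }
  return d;
}
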