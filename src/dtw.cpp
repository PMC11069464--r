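#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Band-constrained DTW (Sakoe-Chiba, |i - j| <= w), squared local cost,
// square root of the accumulated minimum taken at the end so the pointwise
// Euclidean distance is an upper bound and LB_Keogh a lower bound.
// Two-row dynamic programme; O(m * w) time, O(m) space.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericVector q, NumericVector c, int w) {
  const int m = q.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    const int jlo = std::max(1, i - w);
    const int jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double d = q[i - 1] - c[j - 1];
      d *= d;
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// Running min/max envelope over the clipped window [i - w, i + w].
// [[Rcpp::export(name = ".envelope_cpp")]]
List envelope_cpp(NumericVector q, int w) {
  const int m = q.size();
  NumericVector upper(m), lower(m);
  for (int i = 0; i < m; ++i) {
    const int a = std::max(0, i - w);
    const int b = std::min(m - 1, i + w);
    double mx = q[a], mn = q[a];
    for (int j = a + 1; j <= b; ++j) {
      if (q[j] > mx) mx = q[j];
      if (q[j] < mn) mn = q[j];
    }
    upper[i] = mx;
    lower[i] = mn;
  }
  return List::create(Named("upper") = upper, Named("lower") = lower);
}

// LB_Keogh: root of summed squared excursions of the candidate outside the
// query's envelope band.
// [[Rcpp::export(name = ".lb_keogh_cpp")]]
double lb_keogh_cpp(NumericVector t, NumericVector upper, NumericVector lower) {
  const int m = t.size();
  double acc = 0.0;
  for (int i = 0; i < m; ++i) {
    if (t[i] > upper[i]) {
      const double d = t[i] - upper[i];
      acc += d * d;
    } else if (t[i] < lower[i]) {
      const double d = t[i] - lower[i];
      acc += d * d;
    }
  }
  return std::sqrt(acc);
}
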