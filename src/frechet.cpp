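#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete Frechet distance (Eiter-Mannila coupling recurrence) between two
// point sequences with Euclidean ground distance on scaled (t, v) pairs.
// Memory is O(min dimension is not needed): we keep two rows of the lattice.

static inline double ground(double t1, double v1, double t2, double v2,
                            double ts, double vs) {
  double dt = (t1 - t2) * ts;
  double dv = (v1 - v2) * vs;
  return std::sqrt(dt * dt + dv * dv);
}

// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp(NumericVector t1, NumericVector v1,
                  NumericVector t2, NumericVector v2,
                  double time_scale, double value_scale) {
  const int p = t1.size(), q = t2.size();
  std::vector<double> prev(q), cur(q);
  for (int j = 0; j < q; ++j) {
    double d = ground(t1[0], v1[0], t2[j], v2[j], time_scale, value_scale);
    prev[j] = (j == 0) ? d : std::max(prev[j - 1], d);
  }
  for (int i = 1; i < p; ++i) {
    for (int j = 0; j < q; ++j) {
      double d = ground(t1[i], v1[i], t2[j], v2[j], time_scale, value_scale);
      double best;
      if (j == 0) {
        best = prev[0];
      } else {
        best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      }
      cur[j] = std::max(best, d);
    }
    std::swap(prev, cur);
  }
  return prev[q - 1];
}

// All pairwise discrete Frechet distances between the columns of V, every
// curve sampled on the shared grid t.  Returns a symmetric matrix with a
// zero diagonal.

// [[Rcpp::export(name = ".frechet_pairwise_grid")]]
NumericMatrix frechet_pairwise_grid(NumericVector t, NumericMatrix V,
                                    double time_scale, double value_scale) {
  const int n = V.ncol();
  NumericMatrix D(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double d = frechet_dp(t, V(_, a), t, V(_, b), time_scale, value_scale);
      D(a, b) = d;
      D(b, a) = d;
    }
  }
  return D;
}
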