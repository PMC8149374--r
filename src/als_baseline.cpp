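#include <Rcpp.h>
#include <vector>
#include <cmath>

// Asymmetric least squares baseline estimation (Whittaker smoother with
// asymmetric weights). For each spectrum y we iterate
//   z = argmin_z  sum_i w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2
//   w_i = p   if y_i > z_i   (points above the baseline: peaks)
//       = 1-p otherwise
// The normal matrix diag(w) + lambda * D2'D2 is pentadiagonal, so each solve
// is a banded Cholesky factorization, O(m) per iteration per spectrum.

// [[Rcpp::export]]
Rcpp::NumericMatrix als_baseline_cpp(Rcpp::NumericMatrix Y, double lambda,
                                     double p, int n_iter) {
  const int m = Y.nrow(), n = Y.ncol();
  Rcpp::NumericMatrix Z(m, n);
  if (m < 3) {                       // too short to penalize curvature
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i) Z(i, j) = Y(i, j);
    return Z;
  }

  // D2'D2 bands (constant across pixels and iterations)
  std::vector<double> pd0(m, 6.0), pd1(m - 1, -4.0), pd2(m - 2, 1.0);
  pd0[0] = pd0[m - 1] = 1.0;
  pd0[1] = pd0[m - 2] = 5.0;
  pd1[0] = pd1[m - 2] = -2.0;

  std::vector<double> w(m), b(m), z(m);
  std::vector<double> l0(m), l1(m - 1), l2(m - 2); // banded Cholesky factors

  for (int j = 0; j < n; ++j) {
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < n_iter; ++it) {
      // factor C = diag(w) + lambda * D2'D2 = L L' (bandwidth 2)
      for (int i = 0; i < m; ++i) {
        double c0 = w[i] + lambda * pd0[i];
        if (i >= 1) c0 -= l1[i - 1] * l1[i - 1];
        if (i >= 2) c0 -= l2[i - 2] * l2[i - 2];
        l0[i] = std::sqrt(c0);
        if (i + 1 < m) {
          double c1 = lambda * pd1[i];
          if (i >= 1) c1 -= l2[i - 1] * l1[i - 1];
          l1[i] = c1 / l0[i];
        }
        if (i + 2 < m) l2[i] = (lambda * pd2[i]) / l0[i];
      }
      // forward then backward substitution on w .* y
      for (int i = 0; i < m; ++i) {
        double v = w[i] * Y(i, j);
        if (i >= 1) v -= l1[i - 1] * b[i - 1];
        if (i >= 2) v -= l2[i - 2] * b[i - 2];
        b[i] = v / l0[i];
      }
      for (int i = m - 1; i >= 0; --i) {
        double v = b[i];
        if (i + 1 < m) v -= l1[i] * z[i + 1];
        if (i + 2 < m) v -= l2[i] * z[i + 2];
        z[i] = v / l0[i];
      }
      for (int i = 0; i < m; ++i) w[i] = (Y(i, j) > z[i]) ? p : 1.0 - p;
    }
    for (int i = 0; i < m; ++i) Z(i, j) = z[i];
  }
  return Z;
}
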