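#include <Rcpp.h>
using namespace Rcpp;

// Spherical-normal KDE inner loops. Chord-distance Gaussian:
//   f(s) = 1/(n h sqrt(2 pi)) * sum_i exp(-(||s - N_i||^2) / (2 h^2))
// with ||s - N_i||^2 = 2 - 2 <s, N_i> for unit vectors, so the summand is
// exp((<s, N_i> - 1) / h^2).

// [[Rcpp::export(name = ".kde_gaussian")]]
NumericVector kde_gaussian(NumericMatrix grid, NumericMatrix normals,
                           double h) {
  const int k = grid.nrow(), n = normals.nrow();
  NumericVector out(k);
  const double inv_h2 = 1.0 / (h * h);
  const double scale = 1.0 / (n * h * std::sqrt(2.0 * M_PI));
  std::vector<double> nx(n), ny(n), nz(n);
  for (int i = 0; i < n; ++i) {
    nx[i] = normals(i, 0); ny[i] = normals(i, 1); nz[i] = normals(i, 2);
  }
  for (int j = 0; j < k; ++j) {
    const double sx = grid(j, 0), sy = grid(j, 1), sz = grid(j, 2);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dot = sx * nx[i] + sy * ny[i] + sz * nz[i];
      double d2 = 2.0 - 2.0 * dot;
      if (d2 < 0.0) d2 = 0.0;
      acc += std::exp(-0.5 * d2 * inv_h2);
    }
    out[j] = acc * scale;
  }
  return out;
}

// von Mises-Fisher: f(s) = (1/n) sum_i exp(logC + kappa <s, N_i>), where
// logC = log C(kappa) is supplied precomputed in log space for stability.

// [[Rcpp::export(name = ".kde_vmf")]]
NumericVector kde_vmf(NumericMatrix grid, NumericMatrix normals,
                      double kappa, double logC) {
  const int k = grid.nrow(), n = normals.nrow();
  NumericVector out(k);
  std::vector<double> nx(n), ny(n), nz(n);
  for (int i = 0; i < n; ++i) {
    nx[i] = normals(i, 0); ny[i] = normals(i, 1); nz[i] = normals(i, 2);
  }
  for (int j = 0; j < k; ++j) {
    const double sx = grid(j, 0), sy = grid(j, 1), sz = grid(j, 2);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dot = sx * nx[i] + sy * ny[i] + sz * nz[i];
      acc += std::exp(logC + kappa * dot);
    }
    out[j] = acc / n;
  }
  return out;
}
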