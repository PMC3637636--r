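#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Robust/classical scale of a projection.  index_type: 0 = MAD (1.4826
// consistency factor), 1 = sample standard deviation (n-1 denominator).
static double scale_index(std::vector<double> &z, int index_type) {
  const int n = z.size();
  if (index_type == 1) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += z[i];
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (z[i] - m) * (z[i] - m);
    return n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
  }
  // median
  std::vector<double> w(z);
  const int h = n / 2;
  std::nth_element(w.begin(), w.begin() + h, w.end());
  double med = w[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(w.begin(), w.begin() + h);
    med = 0.5 * (med + lo);
  }
  for (int i = 0; i < n; ++i) w[i] = std::fabs(z[i] - med);
  std::nth_element(w.begin(), w.begin() + h, w.end());
  double mad = w[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(w.begin(), w.begin() + h);
    mad = 0.5 * (mad + lo);
  }
  return 1.4826 * mad;
}

// GRID search for the direction maximizing the projection index over the
// unit sphere.  Starts from the best coordinate axis and cycles over
// coordinate planes; the searched angle interval is halved at each cycle.
// [[Rcpp::export(name = ".grid_direction_cpp")]]
List grid_direction_cpp(NumericMatrix Z, int J, int max_cycles,
                        double tol, int index_type) {
  const int n = Z.nrow(), d = Z.ncol();
  std::vector<double> z(n);

  // best single coordinate as the starting direction
  int j0 = 0;
  double best0 = -1.0;
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) z[i] = Z(i, j);
    double s = scale_index(z, index_type);
    if (s > best0) { best0 = s; j0 = j; }
  }
  std::vector<double> a(d, 0.0), u(n);
  a[j0] = 1.0;
  for (int i = 0; i < n; ++i) u[i] = Z(i, j0);
  double cur = best0;

  std::vector<double> cand(n);
  for (int cyc = 1; cyc <= max_cycles; ++cyc) {
    const double hw = M_PI_2 / std::pow(2.0, cyc - 1);
    for (int j = 0; j < d; ++j) {
      double best_s = cur, best_theta = 0.0;
      const double aj = a[j];
      for (int g = 1; g <= J; ++g) {
        const double theta = (-1.0 + 2.0 * g / J) * hw;
        if (std::fabs(theta) < 1e-15) continue;  // current direction
        const double ct = std::cos(theta), st = std::sin(theta);
        const double nrm = std::sqrt(1.0 + 2.0 * ct * st * aj);
        if (nrm < 1e-12) continue;
        for (int i = 0; i < n; ++i)
          cand[i] = (ct * u[i] + st * Z(i, j)) / nrm;
        double s = scale_index(cand, index_type);
        if (s > best_s) { best_s = s; best_theta = theta; }
      }
      if (best_theta != 0.0) {
        const double ct = std::cos(best_theta), st = std::sin(best_theta);
        const double nrm = std::sqrt(1.0 + 2.0 * ct * st * aj);
        for (int k = 0; k < d; ++k) a[k] = ct * a[k] / nrm;
        a[j] += st / nrm;
        for (int i = 0; i < n; ++i) u[i] = (ct * u[i] + st * Z(i, j)) / nrm;
        // renormalise against drift
        double an = 0.0;
        for (int k = 0; k < d; ++k) an += a[k] * a[k];
        an = std::sqrt(an);
        if (std::fabs(an - 1.0) > 1e-9) {
          for (int k = 0; k < d; ++k) a[k] /= an;
          for (int i = 0; i < n; ++i) u[i] /= an;
        }
        cur = best_s;
      }
    }
    // Stop once the angular grid resolution is below tol; a cycle with
    // no accepted move must still continue (the next, halved interval
    // can bracket the optimum more closely).
    if (2.0 * hw / J < tol) break;
  }

  return List::create(_["direction"] = NumericVector(a.begin(), a.end()),
                      _["scale"] = cur);
}

// Column-wise scale index (used by the CR algorithm's candidate sweep).
// [[Rcpp::export(name = ".col_scale_cpp")]]
NumericVector col_scale_cpp(NumericMatrix P, int index_type) {
  const int n = P.nrow(), m = P.ncol();
  NumericVector out(m);
  std::vector<double> z(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) z[i] = P(i, j);
    out[j] = scale_index(z, index_type);
  }
  return out;
}
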