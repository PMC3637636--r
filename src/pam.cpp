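#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Classical PAM (build + swap) on Euclidean dissimilarities with a hard
// iteration cap, so termination is guaranteed on any input (including
// heavily tied or duplicated configurations).
// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix X, int k, int max_swaps = 500) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      const double dist = std::sqrt(s);
      D[(size_t)i * n + j] = dist;
      D[(size_t)j * n + i] = dist;
    }
  }

  std::vector<int> medoids;
  std::vector<char> is_med(n, 0);
  std::vector<double> nearest(n, std::numeric_limits<double>::max());

  // BUILD: greedily add the point with the largest cost reduction
  for (int m = 0; m < k; ++m) {
    int best = -1;
    double best_gain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dd = D[(size_t)c * n + i];
        if (dd < nearest[i]) gain += nearest[i] - dd;
      }
      if (gain > best_gain) { best_gain = gain; best = c; }
    }
    medoids.push_back(best);
    is_med[best] = 1;
    for (int i = 0; i < n; ++i) {
      const double dd = D[(size_t)best * n + i];
      if (dd < nearest[i]) nearest[i] = dd;
    }
  }

  // SWAP: apply the best strictly-improving swap until none remains or
  // the iteration cap is hit
  const double eps = 1e-12;
  for (int it = 0; it < max_swaps; ++it) {
    // nearest and second-nearest medoid distances per point
    std::vector<double> d1(n, std::numeric_limits<double>::max());
    std::vector<double> d2(n, std::numeric_limits<double>::max());
    std::vector<int> m1(n, -1);
    for (int i = 0; i < n; ++i) {
      for (int m = 0; m < k; ++m) {
        const double dd = D[(size_t)medoids[m] * n + i];
        if (dd < d1[i]) { d2[i] = d1[i]; d1[i] = dd; m1[i] = m; }
        else if (dd < d2[i]) d2[i] = dd;
      }
    }
    double best_delta = -eps;
    int best_m = -1, best_h = -1;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      for (int m = 0; m < k; ++m) {
        double delta = 0.0;
        for (int i = 0; i < n; ++i) {
          const double dih = D[(size_t)h * n + i];
          if (m1[i] == m) {
            delta += std::min(dih, d2[i]) - d1[i];
          } else if (dih < d1[i]) {
            delta += dih - d1[i];
          }
        }
        if (delta < best_delta) {
          best_delta = delta; best_m = m; best_h = h;
        }
      }
    }
    if (best_m < 0) break;
    is_med[medoids[best_m]] = 0;
    medoids[best_m] = best_h;
    is_med[best_h] = 1;
  }

  IntegerVector membership(n);
  NumericVector med_out(k);
  double objective = 0.0;
  for (int i = 0; i < n; ++i) {
    double dmin = std::numeric_limits<double>::max();
    int arg = 0;
    for (int m = 0; m < k; ++m) {
      const double dd = D[(size_t)medoids[m] * n + i];
      if (dd < dmin) { dmin = dd; arg = m; }
    }
    membership[i] = arg + 1;
    objective += dmin;
  }
  for (int m = 0; m < k; ++m) med_out[m] = medoids[m] + 1;
  return List::create(_["membership"] = membership,
                      _["medoids"] = med_out,
                      _["objective"] = objective);
}
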