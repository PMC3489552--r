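#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of a vector, R semantics (mean of the two middle order statistics
// for even n). Destroys the input ordering.
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Sum of the h smallest elements. Destroys the input ordering.
static double trimmed_sum_inplace(std::vector<double>& v, int h) {
  std::nth_element(v.begin(), v.begin() + (h - 1), v.end());
  double s = 0.0;
  for (int i = 0; i < h; ++i) s += v[i];
  return s;
}

// Exhaustive (or pre-sampled) search over candidate lines defined by point
// pairs (i1[k], i2[k]) (1-based). criterion: "lms" = median of squared
// residuals, "lts" = sum of the h smallest squared residuals. Ties on the
// criterion break toward the candidate with slope closest to 1.
// [[Rcpp::export]]
List pair_search_fit(NumericVector x, NumericVector y,
                     IntegerVector i1, IntegerVector i2,
                     std::string criterion, int h) {
  const int n = x.size();
  const int m = i1.size();
  const bool lts = (criterion == "lts");
  double best_crit = R_PosInf, best_slope = NA_REAL, best_icpt = NA_REAL;
  double best_tie = R_PosInf;
  std::vector<double> r2(n);
  int n_cand = 0;

  for (int k = 0; k < m; ++k) {
    const int a = i1[k] - 1, b = i2[k] - 1;
    const double dx = x[b] - x[a];
    if (dx == 0.0) continue;
    const double slope = (y[b] - y[a]) / dx;
    const double icpt = y[a] - slope * x[a];
    for (int i = 0; i < n; ++i) {
      const double r = y[i] - icpt - slope * x[i];
      r2[i] = r * r;
    }
    const double crit = lts ? trimmed_sum_inplace(r2, h) : median_inplace(r2);
    const double tie = std::fabs(slope - 1.0);
    ++n_cand;
    const double tol = 1e-12 * (1.0 + std::fabs(best_crit));
    if (crit < best_crit - tol ||
        (std::fabs(crit - best_crit) <= tol && tie < best_tie)) {
      best_crit = crit;
      best_slope = slope;
      best_icpt = icpt;
      best_tie = tie;
    }
  }

  return List::create(_["slope"] = best_slope,
                      _["intercept"] = best_icpt,
                      _["criterion"] = best_crit,
                      _["n_candidates"] = n_cand);
}
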