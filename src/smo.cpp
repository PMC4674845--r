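#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// SMO solver for the C-SVM dual on a precomputed kernel matrix.
// Working-set selection: maximal violating pair (first-order), as in LIBSVM's
// WSS1. Deterministic: no randomness, ties broken by lowest index.
//
// maximize  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
// s.t.      0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label dimension mismatch");
  std::vector<double> alpha(n, 0.0);
  // gradient of the objective w.r.t. alpha (negated dual): G_i = sum_j a_j y_j K_ij - 1
  std::vector<double> G(n, -1.0);
  const double inf = std::numeric_limits<double>::infinity();
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // select i from I_up maximizing -y_i G_i, j from I_low minimizing -y_j G_j
    int i = -1, j = -1;
    double gmax = -inf, gmin = inf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double yi = y[i], yj = y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;
    // unconstrained step along the violating pair
    double delta = (gmax - gmin) / eta; // = (-yi G_i + yj G_j)/eta
    double ai_old = alpha[i], aj_old = alpha[j];
    // Work in the y-scaled variables: d(alpha_i)*yi = -d(alpha_j)*yj
    // Let t = step in (yi*alpha_i) space.
    double t = delta;
    // bounds on t from 0 <= alpha <= C
    double t_hi = inf, t_lo = -inf;
    if (yi == 1) { t_hi = std::min(t_hi, C - ai_old); t_lo = std::max(t_lo, -ai_old); }
    else         { t_hi = std::min(t_hi, ai_old);     t_lo = std::max(t_lo, ai_old - C); }
    if (yj == 1) { t_hi = std::min(t_hi, aj_old);     t_lo = std::max(t_lo, aj_old - C); }
    else         { t_hi = std::min(t_hi, C - aj_old); t_lo = std::max(t_lo, -aj_old); }
    if (t > t_hi) t = t_hi;
    if (t < t_lo) t = t_lo;
    double ai = ai_old + yi * t;
    double aj = aj_old - yj * t;
    const double dai = ai - ai_old, daj = aj - aj_old;
    if (dai == 0 && daj == 0) break;
    alpha[i] = ai; alpha[j] = aj;
    for (int k = 0; k < n; ++k)
      G[k] += y[k] * (K(k, i) * yi * dai + K(k, j) * yj * daj);
  }
  // bias from KKT conditions: average of the violating-pair bounds
  double ub = inf, lb = -inf, sum_free = 0.0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
    const bool free_sv = alpha[t] > 0 && alpha[t] < C;
    if (free_sv) { sum_free += v; ++n_free; }
    if (up)  ub = std::min(ub, -v);
    if (low) lb = std::max(lb, -v);
  }
  // for a free SV t: b = -y_t * G_t (KKT); otherwise midpoint of the bounds
  double b;
  if (n_free > 0) b = sum_free / n_free;
  else b = -(ub + lb) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// Ungapped sliding scan: number of mismatches between `segment` and every
// window of `region` (both plain ACGT strings); returns an integer vector of
// length nchar(region) - nchar(segment) + 1 (empty if region shorter).
// [[Rcpp::export(name = ".sliding_mismatches")]]
IntegerVector sliding_mismatches(std::string region, std::string segment) {
  const int nr = region.size(), ns = segment.size();
  if (ns == 0 || nr < ns) return IntegerVector(0);
  IntegerVector out(nr - ns + 1);
  for (int p = 0; p + ns <= nr; ++p) {
    int mm = 0;
    for (int k = 0; k < ns; ++k) if (region[p + k] != segment[k]) ++mm;
    out[p] = mm;
  }
  return out;
}
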