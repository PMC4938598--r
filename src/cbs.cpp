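#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Minimum pooled sd: guards noise-free (piecewise-exact) inputs where the
// within-split variance is exactly zero but the means differ.
static const double SD_FLOOR = 1e-8;

// Maximal |t|-like statistic over circular arcs of x.
// Candidate arcs: linear windows [i, j] (0-based, inclusive) with
// min_width <= k <= n - min_width, k = j - i + 1.  Every circular arc is
// either such a window or the complement of one, and |Z| is invariant under
// swapping arc and complement, so this enumeration is exhaustive.
// Ties resolved to the smallest start index, then smallest end index: an
// update needs a relative improvement beyond 1e-9, so of numerically tied
// arcs (e.g. an arc and its complement, whose |Z| are mathematically equal
// but accumulate rounding differently) the first in enumeration order wins.
// If t_stop > 0, scanning stops as soon as any |Z| >= t_stop (permutation
// mode: only exceedance matters, not the argmax).
static double max_arc_stat(const double* x, int n, int min_width,
                           double t_stop, int* arc_start, int* arc_end) {
  double S = 0.0, SS = 0.0;
  for (int i = 0; i < n; i++) { S += x[i]; SS += x[i] * x[i]; }
  double best = -1.0;
  int bi = -1, bj = -1;
  const int kmax_global = n - min_width;
  for (int i = 0; i < n; i++) {
    if (i + min_width > n) break;
    double s1 = 0.0, ss1 = 0.0;
    for (int t = i; t < i + min_width - 1; t++) { s1 += x[t]; ss1 += x[t] * x[t]; }
    int kmax = std::min(kmax_global, n - i);
    for (int k = min_width; k <= kmax; k++) {
      const double xv = x[i + k - 1];
      s1 += xv; ss1 += xv * xv;
      const double m1 = s1 / k;
      const double m2 = (S - s1) / (n - k);
      double ssw = (ss1 - k * m1 * m1) + ((SS - ss1) - (n - k) * m2 * m2);
      if (ssw < 0.0) ssw = 0.0;
      double s = std::sqrt(ssw / (n - 2));
      if (s < SD_FLOOR) s = SD_FLOOR;
      const double z = (m1 - m2) / (s * std::sqrt(1.0 / k + 1.0 / (n - k)));
      const double az = std::fabs(z);
      if (az > best * (1.0 + 1e-9)) {
        best = az; bi = i; bj = i + k - 1;
        if (t_stop > 0.0 && best >= t_stop) {
          if (arc_start) *arc_start = bi;
          if (arc_end) *arc_end = bj;
          return best;
        }
      }
    }
  }
  if (arc_start) *arc_start = bi;
  if (arc_end) *arc_end = bj;
  return best < 0.0 ? 0.0 : best;
}

// [[Rcpp::export]]
List cpp_max_arc_stat(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width) stop("need at least 2*min_width markers");
  int bi, bj;
  double T = max_arc_stat(REAL(x), n, min_width, -1.0, &bi, &bj);
  return List::create(_["stat"] = T,
                      _["arc_start"] = bi + 1,
                      _["arc_end"] = bj + 1);
}

// Monte-Carlo permutation p-value with the add-one convention
// p = (1 + #{T_perm >= T_obs}) / (1 + n_perm), early-exiting once p can no
// longer reach alpha.  Uses R's RNG (seed controlled from R).
// [[Rcpp::export]]
List cpp_perm_pvalue_mc(NumericVector x, double t_obs, int min_width,
                        int n_perm, double alpha) {
  const int n = x.size();
  std::vector<double> xb(REAL(x), REAL(x) + n);
  const double thr = t_obs - 1e-12;
  // smallest exceedance count that already forces p > alpha
  int cutoff = (int)std::floor(alpha * (1.0 + n_perm) - 1.0 + 1e-9) + 1;
  if (cutoff < 1) cutoff = 1;
  int count = 0, done = 0;
  bool early = false;
  for (int b = 0; b < n_perm; b++) {
    for (int i = n - 1; i > 0; i--) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xb[i], xb[j]);
    }
    double T = max_arc_stat(xb.data(), n, min_width, thr, nullptr, nullptr);
    if (T >= thr) count++;
    done = b + 1;
    if (count >= cutoff) { early = true; break; }
  }
  double p = (1.0 + count) / (1.0 + done);
  return List::create(_["p"] = p, _["n_used"] = done,
                      _["exceed"] = count, _["early"] = early);
}

// Exact permutation p-value by full enumeration of all n! orderings:
// p = #{T >= T_obs} / n!  (the identity ordering is one of them).
// [[Rcpp::export]]
List cpp_perm_pvalue_exact(NumericVector x, double t_obs, int min_width) {
  const int n = x.size();
  if (n > 10) stop("exact enumeration limited to n <= 10");
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<double> xb(n);
  const double thr = t_obs - 1e-12;
  double count = 0.0, total = 0.0;
  do {
    for (int i = 0; i < n; i++) xb[i] = x[idx[i]];
    double T = max_arc_stat(xb.data(), n, min_width, thr, nullptr, nullptr);
    if (T >= thr) count += 1.0;
    total += 1.0;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return List::create(_["p"] = count / total, _["n_used"] = total,
                      _["exceed"] = count, _["early"] = false);
}
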