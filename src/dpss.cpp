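// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// commuting matrix: bisection with Sturm sequence counts locates the k
// largest eigenvalues, inverse iteration (tridiagonal LU with partial
// pivoting) recovers the eigenvectors.  O(n) per bisection/solve step.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Number of eigenvalues of the tridiagonal (diag d, off-diag e) < x,
// via the classic LDL^T Sturm recurrence with underflow guard.
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  const int n = (int)d.size();
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    double denom = q;
    if (std::fabs(denom) < 1e-300) denom = (denom < 0 ? -1e-300 : 1e-300);
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// Solve (T - shift I) y = b by Gaussian elimination with partial pivoting
// (fill-in limited to a second superdiagonal); overwrites b with y.
static void tridiag_shifted_solve(const std::vector<double>& d,
                                  const std::vector<double>& e,
                                  double shift, std::vector<double>& b) {
  const int n = (int)d.size();
  std::vector<double> a(n), c0(n, 0.0), c1(n, 0.0), c2(n, 0.0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - shift;
  // band storage: c0 = diag, c1 = first super, c2 = second super
  for (int i = 0; i < n; ++i) {
    c0[i] = a[i];
    c1[i] = (i < n - 1) ? e[i] : 0.0;
  }
  std::vector<double> sub(n, 0.0);
  for (int i = 0; i < n - 1; ++i) sub[i] = e[i]; // sub[i] couples row i+1 to i

  for (int i = 0; i < n - 1; ++i) {
    double below = sub[i];
    if (std::fabs(below) > std::fabs(c0[i])) {
      // swap row i and i+1
      std::swap(c0[i], sub[i]);
      double t1 = c1[i]; c1[i] = c0[i + 1]; c0[i + 1] = t1;
      double t2 = c2[i]; c2[i] = c1[i + 1]; c1[i + 1] = t2;
      std::swap(b[i], b[i + 1]);
      below = sub[i];
    }
    double piv = c0[i];
    if (std::fabs(piv) < 1e-300) piv = (piv < 0 ? -1e-300 : 1e-300);
    double m = below / piv;
    c0[i + 1] -= m * c1[i];
    c1[i + 1] -= m * c2[i];
    b[i + 1] -= m * b[i];
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= c1[i] * b[i + 1];
    if (i + 2 < n) s -= c2[i] * b[i + 2];
    double piv = c0[i];
    if (std::fabs(piv) < 1e-300) piv = (piv < 0 ? -1e-300 : 1e-300);
    b[i] = s / piv;
  }
}

// [[Rcpp::export(name = ".dpss_compute")]]
NumericMatrix dpss_compute(int n, double nw, int k) {
  const double W = nw / n;
  std::vector<double> d(n), e(n - 1);
  const double c = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1.0 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 0; i < n - 1; ++i)
    e[i] = (i + 1.0) * (n - 1.0 - i) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = (i > 0 ? std::fabs(e[i - 1]) : 0.0) +
               (i < n - 1 ? std::fabs(e[i]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  double scale = std::max(std::fabs(lo), std::fabs(hi));

  // bisect for eigenvalues with (ascending) indices n-k .. n-1
  NumericVector vals(k);
  for (int j = 0; j < k; ++j) {
    int target = n - 1 - j;      // 0-based ascending index
    double a = lo, b = hi;
    for (int it = 0; it < 120; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) > target) b = mid; else a = mid;
      if (b - a < 1e-14 * scale) break;
    }
    vals[j] = 0.5 * (a + b);
  }

  NumericMatrix V(n, k);
  // deterministic LCG start vectors: keeps the result independent of (and
  // invisible to) R's RNG stream
  unsigned long long s = 88172645463325252ULL;
  for (int j = 0; j < k; ++j) {
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) {
      s = s * 6364136223846793005ULL + 1442695040888963407ULL;
      v[i] = (double)(s >> 11) / 9007199254740992.0 - 0.5;
    }
    for (int iter = 0; iter < 5; ++iter) {
      tridiag_shifted_solve(d, e, vals[j], v);
      // orthogonalize against previously found vectors
      for (int p = 0; p < j; ++p) {
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += v[i] * V(i, p);
        for (int i = 0; i < n; ++i) v[i] -= dot * V(i, p);
      }
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    for (int i = 0; i < n; ++i) V(i, j) = v[i];
  }
  return V;
}
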