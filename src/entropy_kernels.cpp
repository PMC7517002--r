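#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between the length-m templates starting at i and j
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(x[i + k] - x[j + k]);
    if (v > d) d = v;
  }
  return d;
}

// Approximate entropy: Phi_m - Phi_{m+1}, self-matches included, d <= r.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const double* p = REAL(x);
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    const int mm = m + s;
    const int n = N - mm + 1;  // number of templates
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j)
        if (cheb(p, i, j, mm) <= r) ++cnt;  // cnt >= 1 (self-match)
      acc += std::log((double)cnt / n);
    }
    phi[s] = acc / n;
  }
  return phi[0] - phi[1];
}

// Sample entropy, Richman-Moorman form: B and A are match fractions over the
// first N-m templates at dimensions m and m+1, self-matches excluded.
// Returns -ln(A/B); NA when A or B is zero (undefined).
// [[Rcpp::export(name = ".saen_cpp")]]
double saen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const double* p = REAL(x);
  const int n = N - m;  // templates considered at both dimensions
  long long B = 0, A = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (cheb(p, i, j, m) <= r) ++B;
      if (cheb(p, i, j, m + 1) <= r) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy with Gaussian-type membership exp(-ln(2) * (D/r)^2).
// C_i at dimension mm averages memberships over j != i; Phi is the plain
// average of the C_i; result is ln Phi_m - ln Phi_{m+1}.
static double fuen_phi(const double* p, int N, int mm, double r) {
  const int n = N - mm + 1;  // templates at this dimension
  const double lr2 = M_LN2 / (r * r);
  double phi = 0.0;
  for (int i = 0; i < n; ++i) {
    double ci = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = cheb(p, i, j, mm);
      ci += std::exp(-lr2 * d * d);
    }
    phi += ci / (n - 1);
  }
  return phi / n;
}

// [[Rcpp::export(name = ".fuen_cpp")]]
double fuen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const double* p = REAL(x);
  double a = fuen_phi(p, N, m, r);
  double b = fuen_phi(p, N, m + 1, r);
  if (a <= 0.0 || b <= 0.0) return NA_REAL;
  return std::log(a) - std::log(b);
}
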