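#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy of one series, Richman-Moorman convention:
// both template lengths use start indices 0..N-m-1 so that every length-m
// template has a length-(m+1) extension; self-matches excluded; Chebyshev
// distance; r is an absolute tolerance (precomputed from r_frac * pop SD).
// Returns -log(A/B); NA when A == 0 or B == 0 (degenerate).
static double sampen_one(const double *x, const int n, const int m,
                         const double r) {
  const int nt = n - m;  // number of template start positions
  if (nt < 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}

// [[Rcpp::export]]
NumericVector sampen_matrix_cpp(const NumericMatrix &X, const int m,
                                const double r_frac) {
  const int n = X.nrow(), nv = X.ncol();
  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) {
    const double *col = &X(0, v);
    double mean = 0.0;
    for (int t = 0; t < n; ++t) mean += col[t];
    mean /= n;
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      const double d = col[t] - mean;
      ss += d * d;
    }
    const double r = r_frac * std::sqrt(ss / n);  // population SD
    out[v] = sampen_one(col, n, m, r);
  }
  return out;
}

// Raw template-pair counts (A, B) for one series; used for diagnostics and
// the non-negativity property (A <= B).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(const NumericVector &x, const int m,
                                const double r_frac) {
  const int n = x.size();
  double mean = 0.0;
  for (int t = 0; t < n; ++t) mean += x[t];
  mean /= n;
  double ss = 0.0;
  for (int t = 0; t < n; ++t) ss += (x[t] - mean) * (x[t] - mean);
  const double r = r_frac * std::sqrt(ss / n);
  const int nt = n - m;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  return NumericVector::create(_["A"] = (double)A, _["B"] = (double)B);
}
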