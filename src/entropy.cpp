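#include <Rcpp.h>
using namespace Rcpp;

// Template-matching kernels for the regularity entropies. All use the
// Chebyshev (max-norm) distance between delay vectors of length m built
// from consecutive samples.

// Approximate entropy (Pincus): self-matches included, template sets of
// size N-m+1 at length m and N-m at length m+1.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) stop("series too short for embedding dimension m");
  double phi[2];
  for (int k = 0; k < 2; ++k) {
    int mm = m + k;
    int nt = n - mm + 1;            // number of templates
    double sum_log = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        double d = 0.0;
        for (int l = 0; l < mm; ++l) {
          double a = std::fabs(x[i + l] - x[j + l]);
          if (a > d) d = a;
        }
        if (d <= r) ++cnt;          // j == i counts: self-match included
      }
      sum_log += std::log((double)cnt / nt);
    }
    phi[k] = sum_log / nt;
  }
  return phi[0] - phi[1];
}

// Sample entropy (Richman & Moorman): self-matches excluded; both
// template lengths restricted to the first N-m start points so that the
// (m+1)-length vector always exists and A <= B.
// Returns -log(A/B); R_PosInf when A or B is zero.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) stop("series too short for embedding dimension m");
  int nt = n - m;                   // start points 0 .. n-m-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double a = std::fabs(x[i + l] - x[j + l]);
        if (a > d) d = a;
      }
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(x[i + m] - x[j + m]);
        if (a > d) d = a;
        if (d <= r) A += 1.0;
      }
    }
  }
  if (B == 0.0 || A == 0.0) return R_PosInf;
  return -std::log(A / B);
}

// Fuzzy entropy (Chen et al.): templates baseline-removed (own mean
// subtracted), similarity exp(-(d/r)^nf), averaged over ordered i != j
// pairs; N-m templates at both lengths m and m+1.
// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double r, double nf) {
  int n = x.size();
  if (n < m + 2) stop("series too short for embedding dimension m");
  int nt = n - m;                   // templates at both lengths
  double phi[2];
  for (int k = 0; k < 2; ++k) {
    int mm = m + k;
    // baseline-removed templates
    std::vector<double> tpl((size_t)nt * mm);
    for (int i = 0; i < nt; ++i) {
      double mu = 0.0;
      for (int l = 0; l < mm; ++l) mu += x[i + l];
      mu /= mm;
      for (int l = 0; l < mm; ++l) tpl[(size_t)i * mm + l] = x[i + l] - mu;
    }
    double s = 0.0;
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        for (int l = 0; l < mm; ++l) {
          double a = std::fabs(tpl[(size_t)i * mm + l] - tpl[(size_t)j * mm + l]);
          if (a > d) d = a;
        }
        s += std::exp(-std::pow(d / r, nf));
      }
    }
    phi[k] = s / ((double)nt * (nt - 1) / 2.0);
  }
  return std::log(phi[0]) - std::log(phi[1]);
}
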