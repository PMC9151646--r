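#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy. Pairs i < j only (self-matches
// excluded by construction); Chebyshev distance with tolerance r.
// Returns (B, A): matches at embedding length m and m + 1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m;        // number of m-length templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r)
        A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}

// Multivariate sample entropy counts (composite delay vectors, Ahmed-Mandic
// style) for p channels, per-channel embedding m, lag 1. The m-level vector
// stacks m consecutive samples from every channel; the (m+1)-level set
// contains, for each time index, the p vectors obtained by extending one
// channel by one sample. Chebyshev distance across all components.
// Extended-level pairs sharing the time index are excluded (their bases are
// identical, so counting them breaks the conditional-probability reading and
// can push the entropy negative); this generalizes self-match exclusion.
// Returns (B, A, nB, nA): raw match counts and the number of vectors at each
// level, so the caller can normalize to match densities.
// [[Rcpp::export]]
NumericVector msampen_counts(NumericMatrix X, int m, double r) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int nm = n - m;        // composite vectors at level m
  double B = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool match = true;
      for (int c = 0; c < p && match; ++c)
        for (int k = 0; k < m; ++k)
          if (std::fabs(X(i + k, c) - X(j + k, c)) > r) { match = false; break; }
      if (match) B += 1.0;
    }
  }
  // Level m+1: vector (i, e) = level-m vector at i extended by X(i + m, e).
  // Valid only while i + m < n.
  const int ne = n - m;        // candidate time indices; need i + m <= n - 1
  double A = 0.0;
  long nA = 0;
  for (int i = 0; i < ne; ++i) if (i + m < n) nA += p;
  for (int i = 0; i < ne; ++i) {
    if (i + m >= n) continue;
    for (int e1 = 0; e1 < p; ++e1) {
      for (int j = i + 1; j < ne; ++j) {
        if (j + m >= n) continue;
        for (int e2 = 0; e2 < p; ++e2) {
          bool match = true;
          for (int c = 0; c < p && match; ++c)
            for (int k = 0; k < m; ++k)
              if (std::fabs(X(i + k, c) - X(j + k, c)) > r) { match = false; break; }
          if (!match) continue;
          if (std::fabs(X(i + m, e1) - X(j + m, e2)) > r) continue;
          A += 1.0;
        }
      }
    }
  }
  return NumericVector::create(B, A, (double)(nm), (double)nA);
}

static void iir_forward(const std::vector<double>& b, const std::vector<double>& a,
                        std::vector<double>& x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);          // direct form II transposed state
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      z[k] = bk * xi + z[k + 1] - ak * yi;
    }
    if (nz > 0) {
      double bk = (nz < nb) ? b[nz] : 0.0;
      double ak = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bk * xi - ak * yi;
    }
    x[i] = yi;
  }
}

// Zero-phase IIR filtering applied columnwise: odd-reflection padding at both
// ends (3 * filter order), forward pass, time reversal, second pass, reversal,
// unpad. Coefficients normalized so a[0] = 1 by the caller.
// [[Rcpp::export]]
NumericMatrix iir_filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const int npad = 3 * (std::max(bb.size(), aa.size()) - 1);
  if (n <= npad)
    stop("series too short for zero-phase filtering (need > %d samples)", npad);
  NumericMatrix Y(n, p);
  std::vector<double> w(n + 2 * npad);
  for (int c = 0; c < p; ++c) {
    // odd extension: 2*x[0] - x[k] head, 2*x[n-1] - x[k] tail
    for (int k = 0; k < npad; ++k) w[k] = 2.0 * X(0, c) - X(npad - k, c);
    for (int k = 0; k < n; ++k) w[npad + k] = X(k, c);
    for (int k = 0; k < npad; ++k) w[npad + n + k] = 2.0 * X(n - 1, c) - X(n - 2 - k, c);
    iir_forward(bb, aa, w);
    std::reverse(w.begin(), w.end());
    iir_forward(bb, aa, w);
    std::reverse(w.begin(), w.end());
    for (int k = 0; k < n; ++k) Y(k, c) = w[npad + k];
  }
  return Y;
}
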