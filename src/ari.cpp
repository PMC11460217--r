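// Adjusted Rand Index on integer label vectors via the contingency-table
// formula, plus an all-pairs version used for the n x n patient similarity
// matrix. Labels must be coded 0..K-1 (the R wrappers recode).
#include <Rcpp.h>
using namespace Rcpp;

static double ari_from_tables(const std::vector<double>& nij,
                              const std::vector<double>& a,
                              const std::vector<double>& b, int Ka, int Kb,
                              double N, bool identical_labels) {
  auto c2 = [](double x) { return x * (x - 1.0) / 2.0; };
  double sum_nij = 0.0, sum_a = 0.0, sum_b = 0.0;
  for (int i = 0; i < Ka * Kb; ++i) sum_nij += c2(nij[i]);
  for (int i = 0; i < Ka; ++i) sum_a += c2(a[i]);
  for (int j = 0; j < Kb; ++j) sum_b += c2(b[j]);
  double totpairs = c2(N);
  double expected = sum_a * sum_b / totpairs;
  double maxindex = 0.5 * (sum_a + sum_b);
  double denom = maxindex - expected;
  if (denom == 0.0) {
    // both labelings constant: 1 if identical, 0 otherwise
    return identical_labels ? 1.0 : 0.0;
  }
  return (sum_nij - expected) / denom;
}

// [[Rcpp::export]]
double ari_labels_cpp(const IntegerVector& x, const IntegerVector& y, int K) {
  const int N = x.size();
  std::vector<double> nij(K * K, 0.0), a(K, 0.0), b(K, 0.0);
  bool identical_labels = true;
  for (int i = 0; i < N; ++i) {
    nij[x[i] * K + y[i]] += 1.0;
    a[x[i]] += 1.0;
    b[y[i]] += 1.0;
    if (x[i] != y[i]) identical_labels = false;
  }
  return ari_from_tables(nij, a, b, K, K, (double)N, identical_labels);
}

// [[Rcpp::export]]
NumericMatrix ari_pairwise_cpp(const IntegerMatrix& L, int K) {
  // L: N cells x n patients, entries 0..K-1
  const int N = L.nrow(), n = L.ncol();
  NumericMatrix out(n, n);
  std::vector<double> counts(n * K, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < N; ++i) counts[j * K + L(i, j)] += 1.0;
  std::vector<double> nij(K * K);
  for (int j1 = 0; j1 < n; ++j1) {
    out(j1, j1) = 1.0;
    for (int j2 = j1 + 1; j2 < n; ++j2) {
      std::fill(nij.begin(), nij.end(), 0.0);
      bool identical_labels = true;
      for (int i = 0; i < N; ++i) {
        nij[L(i, j1) * K + L(i, j2)] += 1.0;
        if (L(i, j1) != L(i, j2)) identical_labels = false;
      }
      std::vector<double> a(counts.begin() + j1 * K,
                            counts.begin() + (j1 + 1) * K);
      std::vector<double> b(counts.begin() + j2 * K,
                            counts.begin() + (j2 + 1) * K);
      double v = ari_from_tables(nij, a, b, K, K, (double)N, identical_labels);
      out(j1, j2) = v;
      out(j2, j1) = v;
    }
  }
  return out;
}
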