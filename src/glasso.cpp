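// Graphical lasso via block coordinate descent (row-wise lasso regressions
// on the working covariance W), with optional warm starts so that a
// decreasing lambda path can reuse the previous solution.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol,
                     int max_sweeps, Rcpp::Nullable<Rcpp::NumericMatrix> W_init,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init) {
  const int p = S.n_rows;
  mat W(p, p), B(p, p, fill::zeros); // B(,j): lasso coefficients for column j
  // the L1 penalty applies to off-diagonal entries only, so the working
  // covariance keeps the sample diagonal (S = identity then yields K =
  // identity for every lambda)
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
    W.diag() = S.diag();
  } else {
    W = S;
  }
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());

  // convergence on mean absolute change of off-diagonal W, relative to the
  // mean absolute off-diagonal of S (falls back to absolute scale if S is
  // diagonal)
  double s_scale = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_scale += std::fabs(S(i, j));
  s_scale /= std::max(1, p * (p - 1));
  if (s_scale <= 0.0) s_scale = 1.0;
  const double w_thr = tol * s_scale;

  bool converged = false;
  int sweep = 0;
  const int max_inner = 10000;
  for (sweep = 0; sweep < max_sweeps && !converged; ++sweep) {
    double dw_sum = 0.0;
    int dw_n = 0;
    for (int j = 0; j < p; ++j) {
      // indices excluding j
      uvec idx(p - 1);
      for (int k = 0, m = 0; k < p; ++k)
        if (k != j) idx(m++) = k;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      beta = beta(idx);
      // coordinate descent on 0.5 b'W11 b - s12'b + lambda |b|_1
      for (int it = 0; it < max_inner; ++it) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
          double bnew = soft_threshold(r, lambda) / W11(k, k);
          double d = std::fabs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < tol * 1e-2) break;
      }
      vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        dw_sum += std::fabs(W(idx(k), j) - w12(k));
        ++dw_n;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (dw_n == 0 || dw_sum / dw_n < w_thr) converged = true;
  }

  // recover the precision matrix; exact zeros come from the lasso pattern
  mat K(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double w12b = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) w12b += W(k, j) * B(k, j);
    double kjj = 1.0 / (W(j, j) - w12b);
    K(j, j) = kjj;
    for (int k = 0; k < p; ++k)
      if (k != j) K(k, j) = -B(k, j) * kjj;
  }
  // symmetrize, keeping exact zeros where both lasso fits agree on zero
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      if (B(i, j) == 0.0 && B(j, i) == 0.0) {
        K(i, j) = 0.0;
        K(j, i) = 0.0;
      } else {
        double v = 0.5 * (K(i, j) + K(j, i));
        K(i, j) = v;
        K(j, i) = v;
      }
    }

  return Rcpp::List::create(Rcpp::Named("K") = K, Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("sweeps") = sweep);
}
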