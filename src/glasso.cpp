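#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Block coordinate-descent solver for the L1-penalised Gaussian likelihood
//   maximise  log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// (penalty on off-diagonal entries only, so the diagonal of the working
// covariance W stays equal to diag(S)).  Each column update solves a lasso
// problem by cyclic coordinate descent on the dual covariance column.

static double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-4, int max_iter = 500,
                      double inner_tol = 1e-6, int inner_max = 1000) {
  const int p = S.n_rows;
  mat W = S;                       // working covariance estimate
  mat B = zeros<mat>(p - 1 > 0 ? p - 1 : 1, p);  // lasso coefficients per column
  if (p == 1) {
    mat Theta(1, 1); Theta(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                              Rcpp::Named("W") = W,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  const double offdiag_mean =
      accu(abs(S)) - trace(abs(S)) > 0
          ? (accu(abs(S)) - trace(abs(S))) / (p * (p - 1))
          : 1.0;
  const double thresh = tol * std::max(offdiag_mean, 1e-12);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // partition indices: all but j
      uvec idx(p - 1);
      int k = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx(k++) = i;

      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = B.col(j);

      // coordinate descent:  min 1/2 b' W11 b - s12' b + lambda |b|_1
      vec grad_cache = W11 * beta;
      for (int it = 0; it < inner_max; ++it) {
        double inner_delta = 0.0;
        for (int a = 0; a < p - 1; ++a) {
          double old = beta(a);
          double resid = s12(a) - (grad_cache(a) - W11(a, a) * old);
          double bnew = soft_threshold(resid, lambda) / W11(a, a);
          if (bnew != old) {
            grad_cache += W11.col(a) * (bnew - old);
            beta(a) = bnew;
            inner_delta = std::max(inner_delta, std::fabs(bnew - old));
          }
        }
        if (inner_delta < inner_tol) break;
      }
      B.col(j) = beta;

      vec w12 = W11 * beta;
      k = 0;
      double delta = 0.0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        delta = std::max(delta, std::fabs(W(i, j) - w12(k)));
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        ++k;
      }
      max_delta = std::max(max_delta, delta);
    }
    if (max_delta < thresh) { converged = true; break; }
  }

  // recover Theta from W and the lasso coefficients
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    int k = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx(k++) = i;
    vec beta = B.col(j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta_jj;
    k = 0;
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      Theta(i, j) = -beta(k) * theta_jj;
      ++k;
    }
  }
  // symmetrise (numerically) — the estimator is symmetric at convergence
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
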