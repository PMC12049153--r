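#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF for min ||X - W H||_F^2 with W, H >= 0.
// The Frobenius error is tracked each iteration via the trace identity
// ||X - WH||^2 = ||X||^2 - 2 tr(H' W' X) + tr((W'W)(HH')), which reuses
// W'X from the H-update so the stopping rule costs no extra GEMM.
// [[Rcpp::export]]
List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                int max_iter, double tol) {
  const double eps = 1e-10;
  const double x_sq = arma::accu(arma::square(X));
  std::vector<double> err_trace;
  err_trace.reserve(max_iter);
  double err_prev = arma::datum::inf;
  int iters = 0;

  for (int it = 0; it < max_iter; ++it) {
    // H <- H * (W'X) / (W'W H)
    arma::mat WtX = W.t() * X;
    arma::mat WtW = W.t() * W;
    H %= WtX / (WtW * H + eps);

    // error after the H half-step (objective is non-increasing per half-step)
    arma::mat HHt = H * H.t();
    double err = x_sq - 2.0 * arma::accu(WtX % H) + arma::accu(WtW % HHt);
    if (err < 0) err = 0;

    // W <- W * (X H') / (W H H')
    arma::mat XHt = X * H.t();
    W %= XHt / (W * HHt + eps);
    err_trace.push_back(err);
    iters = it + 1;

    if (std::isfinite(err_prev)) {
      double rel = (err_prev - err) / std::max(err_prev, eps);
      if (std::fabs(rel) < tol) break;
    }
    err_prev = err;
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["err"] = NumericVector(err_trace.begin(), err_trace.end()),
                      _["iterations"] = iters);
}

// Lawson-Hanson active-set NNLS on normal equations, solved for every
// column of B against the same design A (m x k, k small).
// Returns the k x n coefficient matrix.
// [[Rcpp::export]]
arma::mat nnls_cpp(const arma::mat& A, const arma::mat& B,
                   double tol_rel = 1e-10, int max_outer = 200) {
  const arma::uword k = A.n_cols, n = B.n_cols;
  arma::mat AtA = A.t() * A;
  arma::mat AtB = A.t() * B;
  arma::mat X(k, n, arma::fill::zeros);
  double tol = tol_rel * std::max(1.0, AtA.max());

  for (arma::uword j = 0; j < n; ++j) {
    arma::vec x(k, arma::fill::zeros);
    arma::vec atb = AtB.col(j);
    std::vector<bool> passive(k, false);
    arma::vec w = atb; // gradient = At(b - Ax) at x = 0
    int outer = 0;

    while (outer++ < max_outer) {
      // pick the most promising inactive variable
      int t = -1;
      double wmax = tol;
      for (arma::uword i = 0; i < k; ++i)
        if (!passive[i] && w(i) > wmax) { wmax = w(i); t = (int)i; }
      if (t < 0) break;
      passive[t] = true;

      // inner loop: solve on the passive set, backtrack if infeasible
      while (true) {
        arma::uvec P(k);
        arma::uword np = 0;
        for (arma::uword i = 0; i < k; ++i) if (passive[i]) P(np++) = i;
        P.resize(np);
        arma::vec z;
        bool ok = arma::solve(z, AtA.submat(P, P), atb.elem(P),
                              arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
        if (!ok) z = arma::pinv(AtA.submat(P, P)) * atb.elem(P);

        if (z.min() > 0) {
          x.zeros();
          x.rows(P) = z;
          break;
        }
        // step toward z until the first passive variable hits zero
        double alpha = arma::datum::inf;
        for (arma::uword idx = 0; idx < np; ++idx) {
          arma::uword i = P(idx);
          if (z(idx) <= 0) {
            double a = x(i) / (x(i) - z(idx));
            if (a < alpha) alpha = a;
          }
        }
        for (arma::uword idx = 0; idx < np; ++idx) {
          arma::uword i = P(idx);
          x(i) += alpha * (z(idx) - x(i));
          if (x(i) <= tol) { x(i) = 0; passive[i] = false; }
        }
      }
      w = atb - AtA * x;
    }
    X.col(j) = x;
  }
  return X;
}
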