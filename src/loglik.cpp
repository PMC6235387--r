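#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Block-diagonal Gaussian log-likelihood for linear-covariance models
// Sigma_b = sum_k theta[k] * V_{b,k}.  Blocks are concatenated: y and X
// hold all rows in block order; vflat holds, per block, K matrices of
// size n_b x n_b (column-major), i.e. n_b*n_b*K numbers per block.
//
// If beta has length ncol(X) it is taken as fixed; if it has length 0 the
// ML beta is profiled out by GLS.  Returns loglik = -Inf with ok = FALSE
// when any block covariance fails the Cholesky factorization (not PD):
// a defined failure signal the optimizer can use.
// [[Rcpp::export(name = ".lincov_loglik_cpp")]]
Rcpp::List lincov_loglik_cpp(const arma::vec& y,
                             const arma::mat& X,
                             const arma::ivec& block_sizes,
                             const arma::vec& vflat,
                             const arma::vec& theta,
                             const arma::vec& beta_fixed) {
  const uword N = y.n_elem;
  const uword p = X.n_cols;
  const uword K = theta.n_elem;
  const bool profile = (beta_fixed.n_elem == 0);

  double logdet = 0.0, ytSiy = 0.0;
  mat XtSiX(p, p, fill::zeros);
  vec XtSiy(p, fill::zeros);

  uword row0 = 0, v0 = 0;
  for (uword b = 0; b < block_sizes.n_elem; ++b) {
    const uword nb = (uword) block_sizes[b];
    if (nb == 0) continue;
    mat S(nb, nb, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      if (theta[k] != 0.0)
        S += theta[k] * mat(const_cast<double*>(vflat.memptr()) + v0 + k * nb * nb,
                            nb, nb, false, true);
    }
    mat L;
    // a singular-but-PSD S (zero Cholesky pivot) is a failure too
    if (!chol(L, S, "lower") || L.diag().min() < 1e-150) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("ok") = false,
                                Rcpp::Named("beta") = Rcpp::NumericVector(0));
    }
    vec yb = y.subvec(row0, row0 + nb - 1);
    if (!profile && p > 0)
      yb -= X.rows(row0, row0 + nb - 1) * beta_fixed;
    vec z = solve(trimatl(L), yb, solve_opts::fast);
    logdet += 2.0 * sum(log(L.diag()));
    ytSiy += dot(z, z);
    if (profile && p > 0) {
      mat Xb = solve(trimatl(L), X.rows(row0, row0 + nb - 1), solve_opts::fast);
      XtSiX += Xb.t() * Xb;
      XtSiy += Xb.t() * z;
    }
    row0 += nb;
    v0 += nb * nb * K;
  }

  double quad = ytSiy;
  vec beta_hat(p, fill::zeros);
  if (profile && p > 0) {
    mat XtSiX_inv;
    if (!inv_sympd(XtSiX_inv, XtSiX)) {
      bool ok_pinv = pinv(XtSiX_inv, XtSiX);
      if (!ok_pinv)
        return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                  Rcpp::Named("ok") = false,
                                  Rcpp::Named("beta") = Rcpp::NumericVector(0));
    }
    beta_hat = XtSiX_inv * XtSiy;
    quad = ytSiy - dot(beta_hat, XtSiy);
  } else if (!profile) {
    beta_hat = beta_fixed;
  }

  const double ll = -0.5 * (N * std::log(2.0 * M_PI) + logdet + quad);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("beta") = Rcpp::wrap(beta_hat));
}
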