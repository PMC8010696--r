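#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Recursive-least-squares fit of y(t) ~ X theta with exponential
// forgetting. X is the (n x p) sinusoidal design matrix shared by all
// columns of Y (n x k); one independent recursion per column. The
// inverse-covariance recursion uses the Sherman-Morrison rank-one
// update, initialised at P0 = init_gain * I, so with lambda = 1 and a
// large init_gain the epoch-end estimate converges to the ordinary
// least-squares projection.
//
// Returns the (p x k) coefficient estimates at the final sample.
// [[Rcpp::export]]
arma::mat rls_fit_cpp(const arma::mat& X, const arma::mat& Y,
                      const double lambda, const double init_gain) {
  const uword n = X.n_rows;
  const uword p = X.n_cols;
  const uword k = Y.n_cols;
  if (Y.n_rows != n) Rcpp::stop("X and Y must have the same number of rows");
  mat theta_out(p, k);
  for (uword c = 0; c < k; ++c) {
    mat P = init_gain * eye<mat>(p, p);
    vec theta(p, fill::zeros);
    for (uword t = 0; t < n; ++t) {
      const rowvec x = X.row(t);
      const vec Px = P * x.t();
      const double denom = lambda + as_scalar(x * Px);
      const vec gain = Px / denom;
      const double err = Y(t, c) - as_scalar(x * theta);
      theta += gain * err;
      P = (P - gain * x * P) / lambda;
      P = 0.5 * (P + P.t()); // keep symmetric against round-off
    }
    theta_out.col(c) = theta;
  }
  return theta_out;
}
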