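// Non-negative least squares for many genes sharing one small design:
// Lawson-Hanson active set per gene, skipped entirely when the
// unconstrained solution is already feasible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec lawson_hanson(const arma::mat& X, const arma::vec& y,
                               const arma::vec& x0, double tol) {
  const arma::uword p = X.n_cols;
  arma::uvec passive(p, arma::fill::zeros);  // 1 = free coordinate
  arma::vec x(p, arma::fill::zeros);
  for (int outer = 0; outer < (int)(3 * p + 30); ++outer) {
    arma::vec w = X.t() * (y - X * x);       // gradient of -0.5 SSE
    double wmax = -1.0;
    arma::uword jmax = 0;
    for (arma::uword j = 0; j < p; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (wmax <= tol) break;                  // KKT satisfied
    passive(jmax) = 1;
    for (int inner = 0; inner < (int)(3 * p + 30); ++inner) {
      arma::uvec idx = arma::find(passive == 1);
      arma::vec z = arma::solve(X.cols(idx), y);
      if (z.min() > 0.0) {
        x.zeros();
        x(idx) = z;
        break;
      }
      // step toward z until the first coordinate hits zero
      double alpha = 1.0;
      for (arma::uword k = 0; k < idx.n_elem; ++k) {
        const double xk = x(idx(k));
        if (z(k) <= 0.0 && xk - z(k) > 0.0) {
          alpha = std::min(alpha, xk / (xk - z(k)));
        }
      }
      for (arma::uword k = 0; k < idx.n_elem; ++k) {
        const arma::uword j = idx(k);
        x(j) += alpha * (z(k) - x(j));
        if (x(j) <= tol) { x(j) = 0.0; passive(j) = 0; }
      }
    }
  }
  (void)x0;
  return x;
}

// Y: samples x genes, X: samples x p; returns p x genes non-negative
// coefficients.
// [[Rcpp::export]]
arma::mat nnls_cpp(const arma::mat& Y, const arma::mat& X) {
  const arma::uword p = X.n_cols, G = Y.n_cols;
  arma::mat B = arma::solve(X.t() * X, X.t() * Y);  // unconstrained start
  const double scale = arma::abs(X).max();
  for (arma::uword g = 0; g < G; ++g) {
    if (B.col(g).min() < 0.0) {
      const double tol = 1e-10 * scale *
        (arma::abs(Y.col(g)).max() + 1.0);
      B.col(g) = lawson_hanson(X, Y.col(g), B.col(g), tol);
    }
  }
  return B;
}
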