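// Huber M-estimation core: per-gene IRLS with MAD scale, shared design.
// Lives in C++ because the permutation detectors refit every gene under
// hundreds of label reshuffles. X'WX is accumulated as a correction to the
// precomputed X'X over the downweighted samples only (w < 1), which for
// well-behaved genes is a small minority of samples.

#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// median of a scratch vector (contents reordered)
static double median_inplace(std::vector<double>& a) {
  const std::size_t n = a.size();
  const std::size_t h = n / 2;
  std::nth_element(a.begin(), a.begin() + h, a.end());
  double m = a[h];
  if (n % 2 == 0) {
    const double lo = *std::max_element(a.begin(), a.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Y: samples x genes, X: samples x p. Returns p x genes coefficients,
// per-gene MAD residual scale and convergence flags.
// [[Rcpp::export]]
List huber_irls_cpp(const arma::mat& Y, const arma::mat& X,
                    double tuning, int max_iter, double tol) {
  const arma::uword S = X.n_rows, p = X.n_cols, G = Y.n_cols;
  arma::mat B(p, G);
  arma::vec scale(G, arma::fill::zeros);
  arma::ivec converged(G, arma::fill::zeros);
  const arma::mat XtX = X.t() * X;
  const arma::mat XtY = X.t() * Y;
  const arma::mat B0 = arma::solve(XtX, XtY);
  arma::vec r(S), b_new(p), rhs(p), b(p), y(S);
  arma::mat A(p, p);
  std::vector<double> ar(S);
  for (arma::uword g = 0; g < G; ++g) {
    y = Y.col(g);
    b = B0.col(g);
    double s = 0.0;
    bool done = false;
    for (int iter = 0; iter < max_iter; ++iter) {
      r = y - X * b;
      double sum_ar = 0.0;
      for (arma::uword j = 0; j < S; ++j) {
        ar[j] = std::abs(r(j));
        sum_ar += ar[j];
      }
      {
        std::vector<double> tmp(ar);
        s = median_inplace(tmp) / 0.6745;
      }
      const double mean_ar = sum_ar / S;
      if (s <= 1e-12 * (mean_ar + 1e-300) || s == 0.0) {
        done = true;  // (near-)exact fit: the current iterate stands
        break;
      }
      const double ks = tuning * s;
      A = XtX;
      rhs = XtY.col(g);
      for (arma::uword j = 0; j < S; ++j) {
        if (ar[j] > ks) {
          const double c = 1.0 - ks / ar[j];
          const double cy = c * y(j);
          for (arma::uword a = 0; a < p; ++a) {
            const double xa = X(j, a);
            rhs(a) -= xa * cy;
            const double cxa = c * xa;
            for (arma::uword d = a; d < p; ++d) A(a, d) -= cxa * X(j, d);
          }
        }
      }
      A = arma::symmatu(A);
      b_new = arma::solve(A, rhs, arma::solve_opts::likely_sympd);
      const double denom = std::max(1.0, arma::abs(b_new).max());
      const double delta = arma::abs(b_new - b).max();
      b = b_new;
      if (delta / denom < tol) {
        done = true;
        break;
      }
    }
    B.col(g) = b;
    scale(g) = s;
    converged(g) = done ? 1 : 0;
  }
  return List::create(_["coef"] = B, _["scale"] = scale,
                      _["converged"] = converged);
}
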