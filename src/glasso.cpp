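// Block coordinate descent for the graphical LASSO (Friedman et al. style):
// maximize log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|.
// Only off-diagonal entries are penalized, so the working covariance keeps
// the sample diagonal exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// coordinate descent for  min_b  1/2 b'Vb - s'b + lambda ||b||_1
static void lasso_cd(const mat& V, const vec& s, vec& b,
                     const double lambda, const int maxit, const double tol) {
  const uword p = b.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      const double old = b(j);
      // partial residual correlation for coordinate j
      const double r = s(j) - dot(V.col(j), b) + V(j, j) * old;
      double bj = 0.0;
      if (r > lambda)       bj = (r - lambda) / V(j, j);
      else if (r < -lambda) bj = (r + lambda) / V(j, j);
      b(j) = bj;
      const double d = std::fabs(bj - old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, const double lambda,
                      const int maxit = 200, const double tol = 1e-6) {
  const uword p = S.n_rows;
  if (S.n_cols != p) Rcpp::stop("S must be square");
  if (any(S.diag() <= 0)) Rcpp::stop("S must have strictly positive diagonal");

  mat W = S;
  // tiny ridge keeps the working covariance invertible for rank-deficient S
  W.diag() += 1e-10 + 1e-10 * mean(S.diag());
  mat B(p - 1, p, fill::zeros);  // column-wise lasso coefficients

  // convergence scale: average absolute off-diagonal of S
  double offsum = accu(abs(S)) - accu(abs(S.diag()));
  double thresh = tol * (p > 1 ? offsum / (p * (p - 1)) : 1.0);
  if (thresh <= 0) thresh = tol;

  bool converged = (p == 1);
  int iter = 0;
  for (iter = 0; iter < maxit && !converged; ++iter) {
    double maxchange = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
      const mat V = W(idx, idx);
      vec s12 = S.col(j);
      s12.shed_row(j);
      vec b = B.col(j);
      lasso_cd(V, s12, b, lambda, 1000, 0.1 * thresh);
      B.col(j) = b;
      const vec w12 = V * b;
      for (uword i = 0; i < p - 1; ++i) {
        const double d = std::fabs(w12(i) - W(idx(i), j));
        if (d > maxchange) maxchange = d;
        W(idx(i), j) = w12(i);
        W(j, idx(i)) = w12(i);
      }
    }
    if (maxchange < thresh) converged = true;
  }

  // recover the precision matrix from the partitioned inverse identities
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    const vec b = B.col(j);
    vec w12(p - 1);
    for (uword i = 0; i < p - 1; ++i) w12(i) = W(idx(i), j);
    const double t22 = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = t22;
    for (uword i = 0; i < p - 1; ++i) Theta(idx(i), j) = -b(i) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("w") = W,
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}
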