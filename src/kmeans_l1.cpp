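// Lloyd-type k-means under the Manhattan (L1) metric: assignment to the
// nearest centroid (ties to the lowest index), centroid update by the
// componentwise median (the exact minimizer of summed L1 distance).
// Data are held transposed (features x rows) so each point is a contiguous
// column.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// n x k matrix of L1 distances from each row of X to each row of C
// [[Rcpp::export]]
arma::mat l1_distmat_cpp(const arma::mat& X, const arma::mat& C) {
  const uword n = X.n_rows, k = C.n_rows, p = X.n_cols;
  if (C.n_cols != p) Rcpp::stop("feature dimension mismatch");
  const mat Xt = X.t();
  const mat Ct = C.t();
  mat D(n, k);
  for (uword c = 0; c < k; ++c)
    for (uword i = 0; i < n; ++i)
      D(i, c) = accu(abs(Xt.col(i) - Ct.col(c)));
  return D;
}

// [[Rcpp::export]]
Rcpp::List kmeans_l1_cpp(const arma::mat& X, const arma::mat& C0,
                         const int maxit = 100) {
  const uword n = X.n_rows, p = X.n_cols, k = C0.n_rows;
  if (C0.n_cols != p) Rcpp::stop("centroid dimension mismatch");
  if (n < k) Rcpp::stop("fewer rows than centroids");

  const mat Xt = X.t();      // p x n
  mat Ct = C0.t();           // p x k
  uvec assign(n, fill::zeros);
  uvec prev(n);
  prev.fill(n + 1);
  vec dmin(n);
  std::vector<double> trace;

  auto assignAll = [&]() {
    for (uword i = 0; i < n; ++i) {
      const double* xi = Xt.colptr(i);
      double best = datum::inf;
      uword arg = 0;
      for (uword c = 0; c < k; ++c) {
        const double* cc = Ct.colptr(c);
        double d = 0.0;
        uword j = 0;
        // early abandonment once the partial sum exceeds the current best
        for (; j + 4 <= p; j += 4) {
          d += std::fabs(xi[j] - cc[j]) + std::fabs(xi[j + 1] - cc[j + 1]) +
               std::fabs(xi[j + 2] - cc[j + 2]) + std::fabs(xi[j + 3] - cc[j + 3]);
          if (d >= best) break;
        }
        if (d < best) {
          for (; j < p; ++j) d += std::fabs(xi[j] - cc[j]);
        }
        if (d < best) { best = d; arg = c; }  // ties keep the lower index
      }
      assign(i) = arg;
      dmin(i) = best;
    }
  };

  int iter = 0;
  for (iter = 0; iter < maxit; ++iter) {
    assignAll();
    // empty clusters: re-seed at the row farthest from its centroid
    for (uword c = 0; c < k; ++c) {
      if (!any(assign == c)) {
        const uword far = dmin.index_max();
        Ct.col(c) = Xt.col(far);
        assign(far) = c;
        dmin(far) = 0.0;
      }
    }
    trace.push_back(accu(dmin));
    if (all(assign == prev)) break;
    prev = assign;
    // componentwise median update
    for (uword c = 0; c < k; ++c) {
      const uvec idx = find(assign == c);
      if (idx.n_elem == 1) Ct.col(c) = Xt.col(idx(0));
      else Ct.col(c) = median(Xt.cols(idx), 1);
    }
  }

  // final assignment pass so assignment, centroids and objective are
  // consistent even when the iteration cap was hit between update and
  // reassignment
  assignAll();
  const double obj = accu(dmin);
  return Rcpp::List::create(
    Rcpp::Named("assignment") = Rcpp::IntegerVector(assign.begin(), assign.end()),
    Rcpp::Named("centroids") = Ct.t(),
    Rcpp::Named("objective") = obj,
    Rcpp::Named("iterations") = iter + 1,
    Rcpp::Named("objectiveTrace") = trace);
}
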