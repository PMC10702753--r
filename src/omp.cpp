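// Orthogonal matching pursuit with incremental Cholesky least squares.
//
// Per iteration: pick the column of A (L2-normalized for the correlation
// step only) most correlated with the residual, append it to the support,
// re-solve the least-squares problem on the raw support columns via a
// rank-one Cholesky update of the Gram matrix, and update the residual.
// Stops at residual_norm <= tol * ||Y|| or |support| = max_atoms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct OmpOut {
  arma::vec estimate;
  arma::uvec support;
  arma::vec rtrace;     // residual norm after each iteration
  double residual_norm;
  int iterations;
};

OmpOut omp_core(const arma::mat& A, const arma::vec& colnorm,
                const arma::vec& y, int max_atoms, double tol) {
  const arma::uword M = A.n_rows, L = A.n_cols;
  OmpOut out;
  out.estimate = arma::zeros<arma::vec>(L);
  out.residual_norm = arma::norm(y, 2);
  out.iterations = 0;

  const double ynorm = out.residual_norm;
  const double tol_abs = tol * ynorm;
  if (ynorm == 0.0) return out;

  std::vector<arma::uword> sup;
  std::vector<double> rtr;
  std::vector<bool> blocked(L, false);   // selected or degenerate columns

  arma::vec r = y;
  arma::mat Lc(max_atoms, max_atoms, arma::fill::zeros);  // Cholesky of Gram
  arma::mat As(M, max_atoms, arma::fill::zeros);          // support columns
  arma::vec bty(max_atoms, arma::fill::zeros);            // As' y
  arma::vec coef;

  while ((int)sup.size() < max_atoms) {
    // correlation against L2-normalized columns
    arma::vec c = A.t() * r;
    double best = -1.0;
    arma::sword bj = -1;
    for (arma::uword j = 0; j < L; ++j) {
      if (blocked[j] || colnorm[j] <= 0.0) continue;
      double v = std::abs(c[j]) / colnorm[j];
      if (v > best) { best = v; bj = (arma::sword)j; }
    }
    if (bj < 0) break;

    const arma::uword k = sup.size();
    arma::vec aj = A.col((arma::uword)bj);
    double d = arma::dot(aj, aj);
    double lam2 = d;
    arma::vec l;
    if (k > 0) {
      arma::vec g = As.cols(0, k - 1).t() * aj;
      l = arma::solve(arma::trimatl(Lc.submat(0, 0, k - 1, k - 1)), g);
      lam2 = d - arma::dot(l, l);
    }
    if (lam2 <= 1e-12 * std::max(d, 1.0)) {
      // numerically dependent on current support: never select it
      blocked[(arma::uword)bj] = true;
      continue;
    }
    blocked[(arma::uword)bj] = true;
    sup.push_back((arma::uword)bj);
    if (k > 0) Lc.submat(k, 0, k, k - 1) = l.t();
    Lc(k, k) = std::sqrt(lam2);
    As.col(k) = aj;
    bty[k] = arma::dot(aj, y);

    // solve (As'As) coef = As'y via the two triangular systems
    arma::uword kk = sup.size();
    arma::vec z = arma::solve(arma::trimatl(Lc.submat(0, 0, kk - 1, kk - 1)),
                              bty.subvec(0, kk - 1));
    coef = arma::solve(arma::trimatu(Lc.submat(0, 0, kk - 1, kk - 1).t()), z);

    r = y - As.cols(0, kk - 1) * coef;
    out.residual_norm = arma::norm(r, 2);
    out.iterations = (int)kk;
    rtr.push_back(out.residual_norm);
    if (out.residual_norm <= tol_abs) break;
  }

  if (!sup.empty()) {
    out.support = arma::uvec(sup);
    out.estimate.elem(out.support) = coef;
  }
  out.rtrace = arma::vec(rtr);
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_omp_single")]]
List cpp_omp_single(const arma::mat& A, const arma::vec& y,
                    int max_atoms, double tol) {
  arma::vec colnorm = arma::sqrt(arma::sum(arma::square(A), 0)).t();
  OmpOut o = omp_core(A, colnorm, y, max_atoms, tol);
  return List::create(
      _["estimate"] = o.estimate,
      _["support"] = IntegerVector(o.support.begin(), o.support.end()),
      _["residual_norm"] = o.residual_norm,
      _["iterations"] = o.iterations,
      _["residual_trace"] = NumericVector(o.rtrace.begin(), o.rtrace.end()));
}

// Column-wise OMP over a matrix of measurement vectors (one per block).
// [[Rcpp::export(name = ".cpp_omp_batch")]]
arma::mat cpp_omp_batch(const arma::mat& A, const arma::mat& Y,
                        int max_atoms, double tol) {
  arma::vec colnorm = arma::sqrt(arma::sum(arma::square(A), 0)).t();
  arma::mat V(A.n_cols, Y.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    OmpOut o = omp_core(A, colnorm, Y.col(j), max_atoms, tol);
    V.col(j) = o.estimate;
  }
  return V;
}
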