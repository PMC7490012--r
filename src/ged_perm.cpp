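// Permutation engine for the GED eigenvalue significance test.
// Trial-label swaps, covariance re-averaging and the generalized
// eigendecomposition are done here because the calibration studies run
// hundreds of thousands of 16x16 eigensolves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec ged_eigenvalues(const arma::mat& S, const arma::mat& R,
                                 double shrinkage) {
  arma::mat Rs = R;
  if (shrinkage > 0.0) {
    double md = arma::mean(Rs.diag());
    Rs = (1.0 - shrinkage) * Rs +
         shrinkage * md * arma::eye<arma::mat>(Rs.n_rows, Rs.n_cols);
  }
  arma::mat U = arma::chol(Rs);            // R = U' U
  arma::mat Uinv = arma::inv(arma::trimatu(U));
  arma::mat C = Uinv.t() * S * Uinv;
  C = 0.5 * (C + C.t());
  arma::vec ev;
  arma::eig_sym(ev, C);                    // ascending
  return arma::sort(ev, "descend");
}

// Ms, Mr: (n*n) x n_trials flattened per-trial covariance stacks.
// Each permutation swaps a trial's S/R labels independently with
// probability 1/2, re-averages, and solves the GED. Returns n x n_perm
// matrix of descending eigenvalues. Uses R's RNG (seed via set.seed).
// [[Rcpp::export]]
arma::mat cpp_perm_ged_eigs(const arma::mat& Ms, const arma::mat& Mr,
                            int n, int n_perm, double shrinkage) {
  const int n_trials = Ms.n_cols;
  if (Mr.n_cols != (unsigned)n_trials)
    stop("stimulus and baseline stacks have different trial counts");
  if (n_trials < 1) stop("no trials");
  arma::mat out(n, n_perm);
  arma::vec flat_s(n * n), flat_r(n * n);
  for (int p = 0; p < n_perm; ++p) {
    flat_s.zeros();
    flat_r.zeros();
    for (int t = 0; t < n_trials; ++t) {
      bool swap = unif_rand() < 0.5;
      if (swap) {
        flat_s += Mr.col(t);
        flat_r += Ms.col(t);
      } else {
        flat_s += Ms.col(t);
        flat_r += Mr.col(t);
      }
    }
    arma::mat Sb(flat_s.memptr(), n, n);
    arma::mat Rb(flat_r.memptr(), n, n);
    Sb /= n_trials;
    Rb /= n_trials;
    out.col(p) = ged_eigenvalues(Sb, Rb, shrinkage);
  }
  return out;
}
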