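// Largest eigenvalue of a stack of Hermitian matrices (one per TF point).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec largestEigHerm(const arma::cx_cube& sigma) {
  const arma::uword P = sigma.n_slices;
  arma::vec out(P);
  arma::vec ev;
  for (arma::uword p = 0; p < P; ++p) {
    if (!arma::eig_sym(ev, sigma.slice(p)))
      Rcpp::stop("eigenvalue decomposition failed");
    out(p) = ev(ev.n_elem - 1);
  }
  return out;
}
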