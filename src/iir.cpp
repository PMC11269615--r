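// Direct-form II transposed IIR filtering of each column of a matrix.
// Backs the zero-phase (forward-backward) filtering used by the
// preprocessing chain.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".cpp_iir_df2t")]]
arma::mat cpp_iir_df2t(const arma::vec& b, const arma::vec& a,
                       const arma::mat& X) {
  const int nf = std::max(b.n_elem, a.n_elem);
  arma::vec bb(nf, arma::fill::zeros), aa(nf, arma::fill::zeros);
  for (arma::uword i = 0; i < b.n_elem; ++i) bb(i) = b(i) / a(0);
  for (arma::uword i = 0; i < a.n_elem; ++i) aa(i) = a(i) / a(0);
  const int n = X.n_rows, m = X.n_cols;
  arma::mat Y(n, m);
  const double* bp = bb.memptr();
  const double* ap = aa.memptr();
  std::vector<double> z(nf - 1);
  for (int j = 0; j < m; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    const double* x = X.colptr(j);
    double* y = Y.colptr(j);
    for (int t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = bp[0] * xt + z[0];
      for (int i = 0; i < nf - 2; ++i) {
        z[i] = bp[i + 1] * xt + z[i + 1] - ap[i + 1] * yt;
      }
      z[nf - 2] = bp[nf - 1] * xt - ap[nf - 1] * yt;
      y[t] = yt;
    }
  }
  return Y;
}
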