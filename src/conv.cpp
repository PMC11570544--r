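// Convolution kernels for the CPU NN core. Feature maps are (N*H*W) x C
// matrices (row-major pixel order within an image). The im2col index matrix
// is precomputed in R: (Ho*Wo) x (k*k), 0-based into one image's pixel rows,
// -1 marking zero padding. Column layout of the implicit im2col matrix is
// j = kk + k2 * ci (kernel offset fastest), matching the R-side weight
// layout (k2*Cin) x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_one(const mat& xn, const imat& idx, int k2) {
  const int nOut = idx.n_rows;
  const int C = xn.n_cols;
  mat cols(nOut, k2 * C);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = xn.colptr(ci);
    for (int kk = 0; kk < k2; ++kk) {
      double* dst = cols.colptr(kk + k2 * ci);
      const int* ip = idx.colptr(kk);
      for (int r = 0; r < nOut; ++r) {
        const int i = ip[r];
        dst[r] = (i >= 0) ? xc[i] : 0.0;
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".convForwardCpp")]]
arma::mat convForwardCpp(const arma::mat& x, int N, int HW,
                         const arma::imat& idx, const arma::mat& Wm,
                         const arma::vec& b) {
  const int k2 = idx.n_cols;
  const int nOut = idx.n_rows;
  const int Cout = Wm.n_cols;
  mat y(N * nOut, Cout);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col_one(x.rows(n * HW, (n + 1) * HW - 1), idx, k2);
    y.rows(n * nOut, (n + 1) * nOut - 1) = cols * Wm;
  }
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
Rcpp::List convBackwardCpp(const arma::mat& x, const arma::mat& dY, int N,
                           int HW, const arma::imat& idx,
                           const arma::mat& Wm) {
  const int k2 = idx.n_cols;
  const int nOut = idx.n_rows;
  const int Cin = x.n_cols;
  mat dW(Wm.n_rows, Wm.n_cols, fill::zeros);
  mat dX(x.n_rows, Cin, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const mat xn = x.rows(n * HW, (n + 1) * HW - 1);
    const mat dYn = dY.rows(n * nOut, (n + 1) * nOut - 1);
    mat cols = im2col_one(xn, idx, k2);
    dW += cols.t() * dYn;
    mat dcols = dYn * Wm.t();
    for (int ci = 0; ci < Cin; ++ci) {
      double* dxc = dX.colptr(ci) + n * HW;
      for (int kk = 0; kk < k2; ++kk) {
        const double* src = dcols.colptr(kk + k2 * ci);
        const int* ip = idx.colptr(kk);
        for (int r = 0; r < nOut; ++r) {
          const int i = ip[r];
          if (i >= 0) dxc[i] += src[r];
        }
      }
    }
  }
  rowvec db = sum(dY, 0);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = vec(db.t()));
}
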