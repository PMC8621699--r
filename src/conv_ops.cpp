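// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 1-D cross-correlation over multi-channel inputs, vectorized via im2col +
// BLAS gemm. Tensor layout matches R arrays dim c(Cin, L, B) (column-major),
// i.e. an arma::cube with n_rows = Cin, n_cols = L, n_slices = B.
// Weight layout: W is (Cout, Cin*k) with column index cin + Cin*kk
// (channel fastest), matching arma::vectorise of a Cin x k block.
// im2col/col2im move whole kernel-offset blocks (k block copies) rather
// than per-position columns.

static arma::mat im2col(const arma::mat& x, int k, int Lout) {
  const int Cin = x.n_rows;
  arma::mat out(Cin * k, Lout);
  for (int kk = 0; kk < k; ++kk)
    out.rows(kk * Cin, (kk + 1) * Cin - 1) = x.cols(kk, kk + Lout - 1);
  return out;
}

// [[Rcpp::export(name = ".conv1d_fw")]]
arma::cube conv1d_fw(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k) {
  const int B = x.n_slices, Cout = W.n_rows;
  const int Lout = (int)x.n_cols - k + 1;
  arma::cube out(Cout, Lout, B);
  for (int s = 0; s < B; ++s) {
    out.slice(s) = W * im2col(x.slice(s), k, Lout);
    out.slice(s).each_col() += b;
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_bw")]]
List conv1d_bw(const arma::cube& x, const arma::mat& W, const arma::cube& dout,
               int k, bool need_dx) {
  const int B = x.n_slices, Cin = x.n_rows, L = x.n_cols;
  const int Lout = L - k + 1;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::cube dx;
  if (need_dx) dx.zeros(Cin, L, B);
  for (int s = 0; s < B; ++s) {
    arma::mat xc = im2col(x.slice(s), k, Lout);
    const arma::mat& g = dout.slice(s);
    dW += g * xc.t();
    db += arma::sum(g, 1);
    if (need_dx) {
      arma::mat dxc = W.t() * g;  // (Cin*k) x Lout
      for (int kk = 0; kk < k; ++kk)
        dx.slice(s).cols(kk, kk + Lout - 1) +=
            dxc.rows(kk * Cin, (kk + 1) * Cin - 1);
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
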