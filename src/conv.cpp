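// 3x3 "same" convolution kernels for the U-Net segmenter.
//
// Activations are (H*W) x C matrices, spatial index column-major (row
// fastest), matching the R side. Weight matrices have rows ordered
// (ci-1)*9 + k, where k runs column-major over the 3x3 window
// (dr = -1,0,1 fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col: gather the 9 shifted copies of X into Xc (HW x 9*Cin), with
// zero padding outside the image.
static void im2col(const mat& X, int H, int W, mat& Xc) {
  const int Cin = X.n_cols;
  Xc.zeros(H * W, 9 * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X.colptr(ci);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        double* dst = Xc.colptr(ci * 9 + k);
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          const double* s = src + (c + dc) * H + (r0 + dr);
          double* d = dst + c * H + r0;
          std::copy(s, s + (r1 - r0), d);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cppConvFwd")]]
arma::mat cppConvFwd(const arma::mat& X, int H, int W,
                     const arma::mat& Wm, const arma::vec& b) {
  mat Xc;
  im2col(X, H, W, Xc);
  mat Y = Xc * Wm;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".cppConvBwd")]]
Rcpp::List cppConvBwd(const arma::mat& X, const arma::mat& dY, int H,
                      int W, const arma::mat& Wm) {
  const int Cin = X.n_cols;
  mat Xc;
  im2col(X, H, W, Xc);
  mat dW = Xc.t() * dY;
  vec db = sum(dY, 0).t();
  mat dXc = dY * Wm.t();
  // col2im: scatter-add the 9 shifted copies back
  mat dX(H * W, Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = dX.colptr(ci);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        const double* src = dXc.colptr(ci * 9 + k);
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          const double* s = src + c * H + r0;
          double* d = dst + (c + dc) * H + (r0 + dr);
          for (int r = 0; r < r1 - r0; ++r) d[r] += s[r];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
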