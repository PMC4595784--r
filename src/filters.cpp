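// Low-level image filtering primitives backing the S1 stage.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// 'same'-size linear convolution with zero padding.
// [[Rcpp::export]]
arma::mat conv2_same(const arma::mat& img, const arma::mat& kern) {
  return arma::conv2(img, kern, "same");
}

// Local sum over an odd w x w window centred on each pixel ('same' size,
// zero outside the image), via an integral image.
// [[Rcpp::export]]
arma::mat box_sum(const arma::mat& img, const int w) {
  if (w % 2 == 0) Rcpp::stop("box_sum window must be odd");
  const int H = img.n_rows, W = img.n_cols, r = (w - 1) / 2;
  arma::mat I(H + 1, W + 1, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < H; ++i) {
      colsum += img(i, j);
      I(i + 1, j + 1) = I(i + 1, j) + colsum;
    }
  }
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    int c0 = std::max(0, j - r), c1 = std::min(W - 1, j + r);
    for (int i = 0; i < H; ++i) {
      int r0 = std::max(0, i - r), r1 = std::min(H - 1, i + r);
      out(i, j) = I(r1 + 1, c1 + 1) - I(r0, c1 + 1) - I(r1 + 1, c0) + I(r0, c0);
    }
  }
  return out;
}
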