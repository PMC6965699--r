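// im2col / col2im kernels backing the convolution layers. Tensors are
// channel-first: 2D feature maps are (C, H, W, N) arrays, 3D maps are
// (C, D, H, W, N), stored column-major as R arrays. Convolutions are
// 'same' (stride 1, zero padding (k-1)/2), so a k x k convolution is the
// GEMM  W[F x C*k*k] %*% im2col(x)[C*k*k x H*W*N].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat im2col2_cpp(const arma::vec& x, int C, int H, int W, int N, int k) {
  int pad = (k - 1) / 2;
  arma::mat cols(C * k * k, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t col = h + (size_t)H * (w + (size_t)W * n);
        for (int kw = 0; kw < k; ++kw) {
          int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hs = h + kh - pad;
            if (hs < 0 || hs >= H) continue;
            size_t src = (size_t)C * (hs + (size_t)H * (ws + (size_t)W * n));
            size_t row = (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) cols(row + c, col) = x[src + c];
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::vec col2im2_cpp(const arma::mat& cols, int C, int H, int W, int N,
                      int k) {
  int pad = (k - 1) / 2;
  arma::vec out((size_t)C * H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t col = h + (size_t)H * (w + (size_t)W * n);
        for (int kw = 0; kw < k; ++kw) {
          int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hs = h + kh - pad;
            if (hs < 0 || hs >= H) continue;
            size_t dst = (size_t)C * (hs + (size_t)H * (ws + (size_t)W * n));
            size_t row = (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) out[dst + c] += cols(row + c, col);
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
arma::mat im2col3_cpp(const arma::vec& x, int C, int D, int H, int W, int N,
                      int k) {
  int pad = (k - 1) / 2;
  arma::mat cols((size_t)C * k * k * k, (size_t)D * H * W * N,
                 arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          size_t col =
              d + (size_t)D * (h + (size_t)H * (w + (size_t)W * n));
          for (int kw = 0; kw < k; ++kw) {
            int ws = w + kw - pad;
            if (ws < 0 || ws >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hs = h + kh - pad;
              if (hs < 0 || hs >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                int ds = d + kd - pad;
                if (ds < 0 || ds >= D) continue;
                size_t src =
                    (size_t)C *
                    (ds + (size_t)D *
                              (hs + (size_t)H * (ws + (size_t)W * n)));
                size_t row = (size_t)C * (kd + k * (kh + k * kw));
                for (int c = 0; c < C; ++c) cols(row + c, col) = x[src + c];
              }
            }
          }
        }
  return cols;
}

// [[Rcpp::export]]
arma::vec col2im3_cpp(const arma::mat& cols, int C, int D, int H, int W,
                      int N, int k) {
  int pad = (k - 1) / 2;
  arma::vec out((size_t)C * D * H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          size_t col =
              d + (size_t)D * (h + (size_t)H * (w + (size_t)W * n));
          for (int kw = 0; kw < k; ++kw) {
            int ws = w + kw - pad;
            if (ws < 0 || ws >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hs = h + kh - pad;
              if (hs < 0 || hs >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                int ds = d + kd - pad;
                if (ds < 0 || ds >= D) continue;
                size_t dst =
                    (size_t)C *
                    (ds + (size_t)D *
                              (hs + (size_t)H * (ws + (size_t)W * n)));
                size_t row = (size_t)C * (kd + k * (kh + k * kw));
                for (int c = 0; c < C; ++c) out[dst + c] += cols(row + c, col);
              }
            }
          }
        }
  return out;
}
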