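#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for 2-D convolution on arrays laid out as
// (H, W, C, N) in R's column-major order.  Rows of the result are
// kernel entries ordered (kh, kw, c); columns are output positions
// ordered (oh, ow, n).  Zero padding outside the frame.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  const int M = oH * oW * N;
  NumericMatrix cols(K, M);
  const double *px = x.begin();
  double *pc = cols.begin();

  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const int m = oh + oH * (ow + (long)oW * n);
        double *col = pc + (long)K * m;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *xc = px + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = w0 + j;
            const bool win = (w >= 0 && w < W);
            for (int i = 0; i < kh; ++i) {
              const int h = h0 + i;
              const int k = i + kh * (j + kw * c);
              col[k] = (win && h >= 0 && h < H) ? xc[h + (long)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add columns back into an (H, W, C, N)
// array.  Used for convolution input gradients and the transposed
// convolution forward pass.

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  NumericVector x((long)H * W * C * N);
  const double *pc = cols.begin();
  double *px = x.begin();

  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const int m = oh + oH * (ow + (long)oW * n);
        const double *col = pc + (long)K * m;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *xc = px + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = w0 + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int h = h0 + i;
              if (h < 0 || h >= H) continue;
              xc[h + (long)H * w] += col[i + kh * (j + kw * c)];
            }
          }
        }
      }
    }
  }
  return x;
}
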