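#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are column-major (H, W, N, C) arrays. The im2col matrix for a
// 3x3 kernel with dilation d (zero padding = d, stride 1) has one row per
// (h, w, n) and one column per (tap, channel): column index = t*C + c with
// taps ordered i (kernel row) fastest, matching the weight matrix layout
// assembled on the R side.

// [[Rcpp::export(name = ".im2col3x3")]]
NumericMatrix im2col3x3(NumericVector x, int H, int W, int N, int C, int d) {
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix M(rows, (R_xlen_t)C * 9);
  const double* xp = x.begin();
  double* mp = M.begin();
  for (int t = 0; t < 9; ++t) {
    const int oh = (t % 3 - 1) * d;   // kernel row offset
    const int ow = (t / 3 - 1) * d;   // kernel col offset
    const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
    for (int c = 0; c < C; ++c) {
      double* col = mp + ((R_xlen_t)t * C + c) * rows;
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const int sw = w + ow;
          if (sw < 0 || sw >= W || h1 <= h0) continue;
          const double* src = xp + (R_xlen_t)h0 + oh +
            (R_xlen_t)H * (sw + (R_xlen_t)W * (n + (R_xlen_t)N * c));
          double* dst = col + (R_xlen_t)h0 + (R_xlen_t)H * (w + (R_xlen_t)W * n);
          std::memcpy(dst, src, sizeof(double) * (h1 - h0));
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col3x3: scatter-add the column-matrix gradient back to the
// (H, W, N, C) input gradient.

// [[Rcpp::export(name = ".col2im3x3")]]
NumericVector col2im3x3(NumericMatrix gM, int H, int W, int N, int C, int d) {
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector gx((R_xlen_t)H * W * N * C);
  const double* mp = gM.begin();
  double* gp = gx.begin();
  for (int t = 0; t < 9; ++t) {
    const int oh = (t % 3 - 1) * d;
    const int ow = (t / 3 - 1) * d;
    const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
    for (int c = 0; c < C; ++c) {
      const double* col = mp + ((R_xlen_t)t * C + c) * rows;
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const int sw = w + ow;
          if (sw < 0 || sw >= W || h1 <= h0) continue;
          double* dst = gp + (R_xlen_t)h0 + oh +
            (R_xlen_t)H * (sw + (R_xlen_t)W * (n + (R_xlen_t)N * c));
          const double* src = col + (R_xlen_t)h0 + (R_xlen_t)H * (w + (R_xlen_t)W * n);
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  return gx;
}
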