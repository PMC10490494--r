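#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Activation layout used throughout the network engine: a batch of N
// feature maps of size H x W with C channels is a (H*W*N) x C matrix
// whose row index is h + H*w + H*W*n (0-based, column-major within an
// image, images stacked). This keeps every per-channel op a plain
// column op and turns convolution into one GEMM against an im2col
// patch matrix. The h-innermost runs are contiguous in memory, so the
// kernels below move them with std::copy / pointer loops.

// im2col for a k x k 'same' convolution with zero padding p = (k-1)/2.
// Returns (H*W*N) x (k*k*C); column index is dh + k*dw + k*k*c.
// [[Rcpp::export]]
NumericMatrix im2col_nchw(const NumericMatrix& A, int H, int W, int N, int k) {
  const int C = A.ncol();
  const int p = (k - 1) / 2;
  const int HW = H * W;
  const int rows = HW * N;
  NumericMatrix out(rows, k * k * C);
  const double* a0 = &A(0, 0);
  double* o0 = &out(0, 0);
  for (int c = 0; c < C; ++c) {
    const double* ac = a0 + (size_t)c * rows;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* oc = o0 + (size_t)(dh + k * dw + k * k * c) * rows;
        const int h0 = std::max(0, p - dh);
        const int h1 = std::min(H, H + p - dh);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw - p;
            if (ws < 0 || ws >= W) continue;
            double* dst = oc + H * w + HW * n + h0;
            const double* src = ac + H * ws + HW * n + h0 + dh - p;
            std::copy(src, src + (h1 - h0), dst);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_nchw: scatter-add a (H*W*N) x (k*k*C) gradient
// back onto the (H*W*N) x C input layout.
// [[Rcpp::export]]
NumericMatrix col2im_nchw(const NumericMatrix& Acol, int H, int W, int N,
                          int C, int k) {
  const int p = (k - 1) / 2;
  const int HW = H * W;
  const int rows = HW * N;
  NumericMatrix out(rows, C);
  const double* g0 = &Acol(0, 0);
  double* o0 = &out(0, 0);
  for (int c = 0; c < C; ++c) {
    double* oc = o0 + (size_t)c * rows;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* gc = g0 + (size_t)(dh + k * dw + k * k * c) * rows;
        const int h0 = std::max(0, p - dh);
        const int h1 = std::min(H, H + p - dh);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dw - p;
            if (ws < 0 || ws >= W) continue;
            const double* src = gc + H * w + HW * n + h0;
            double* dst = oc + H * ws + HW * n + h0 + dh - p;
            const int len = h1 - h0;
            for (int h = 0; h < len; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling with stride 2. H and W must be even. Returns the
// pooled (H/2*W/2*N) x C matrix and the 1-based input row index of
// each maximum (ties -> earliest row, i.e. top-left first).
// [[Rcpp::export]]
List maxpool2_fwd(const NumericMatrix& A, int H, int W, int N) {
  const int C = A.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  const int rowsIn = HW * N, rowsOut = HWo * N;
  NumericMatrix out(rowsOut, C);
  IntegerMatrix idx(rowsOut, C);
  const double* a0 = &A(0, 0);
  double* o0 = &out(0, 0);
  int* i0 = &idx(0, 0);
  for (int c = 0; c < C; ++c) {
    const double* ac = a0 + (size_t)c * rowsIn;
    double* oc = o0 + (size_t)c * rowsOut;
    int* ic = i0 + (size_t)c * rowsOut;
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int inbase = H * 2 * wo + HW * n;
        const int outbase = Ho * wo + HWo * n;
        for (int ho = 0; ho < Ho; ++ho) {
          const int r0 = inbase + 2 * ho;
          const int cand[4] = {r0, r0 + 1, r0 + H, r0 + H + 1};
          int best = cand[0];
          double bv = ac[best];
          for (int q = 1; q < 4; ++q) {
            if (ac[cand[q]] > bv) { bv = ac[cand[q]]; best = cand[q]; }
          }
          oc[outbase + ho] = bv;
          ic[outbase + ho] = best + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Route pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericMatrix maxpool2_bwd(const NumericMatrix& dOut, const IntegerMatrix& idx,
                           int rowsIn) {
  const int C = dOut.ncol();
  const int rowsOut = dOut.nrow();
  NumericMatrix dA(rowsIn, C);
  const double* g0 = &dOut(0, 0);
  const int* i0 = &idx(0, 0);
  double* o0 = &dA(0, 0);
  for (int c = 0; c < C; ++c) {
    const double* gc = g0 + (size_t)c * rowsOut;
    const int* ic = i0 + (size_t)c * rowsOut;
    double* oc = o0 + (size_t)c * rowsIn;
    for (int r = 0; r < rowsOut; ++r) oc[ic[r] - 1] += gc[r];
  }
  return dA;
}

// 2x2 stride-2 transposed convolution, scatter step. Y4 holds, for each
// input pixel, the F outputs of each of the 4 kernel taps with column
// layout f + F*q, q = dh + 2*dw. Output is the (2H*2W*N) x F map.
// [[Rcpp::export]]
NumericMatrix upconv2_scatter(const NumericMatrix& Y4, int H, int W, int N,
                              int F) {
  const int Ho = 2 * H;
  const int HW = H * W, HWo = 4 * HW;
  const int rowsIn = HW * N, rowsOut = HWo * N;
  NumericMatrix out(rowsOut, F);
  const double* y0 = &Y4(0, 0);
  double* o0 = &out(0, 0);
  for (int f = 0; f < F; ++f) {
    double* of = o0 + (size_t)f * rowsOut;
    for (int q = 0; q < 4; ++q) {
      const int dh = q % 2, dw = q / 2;
      const double* yc = y0 + (size_t)(f + F * q) * rowsIn;
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const double* src = yc + H * w + HW * n;
          double* dst = of + (size_t)(2 * w + dw) * Ho + HWo * n + dh;
          for (int h = 0; h < H; ++h) dst[2 * h] = src[h];
        }
      }
    }
  }
  return out;
}

// Gather step (exact adjoint of upconv2_scatter).
// [[Rcpp::export]]
NumericMatrix upconv2_gather(const NumericMatrix& dOut, int H, int W, int N,
                             int F) {
  const int Ho = 2 * H;
  const int HW = H * W, HWo = 4 * HW;
  const int rowsIn = HW * N, rowsOut = HWo * N;
  NumericMatrix dY4(rowsIn, 4 * F);
  const double* g0 = &dOut(0, 0);
  double* y0 = &dY4(0, 0);
  for (int f = 0; f < F; ++f) {
    const double* gf = g0 + (size_t)f * rowsOut;
    for (int q = 0; q < 4; ++q) {
      const int dh = q % 2, dw = q / 2;
      double* yc = y0 + (size_t)(f + F * q) * rowsIn;
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          double* dst = yc + H * w + HW * n;
          const double* src = gf + (size_t)(2 * w + dw) * Ho + HWo * n + dh;
          for (int h = 0; h < H; ++h) dst[h] = src[2 * h];
        }
      }
    }
  }
  return dY4;
}
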