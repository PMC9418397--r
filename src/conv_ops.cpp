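// Hot inner loops of the CNN: im2col / col2im with implicit zero padding
// and 2x2 max pooling. Activations are (H*W*B) x C matrices, row index
// ordered (h, w, b) with h fastest; patch-matrix columns are ordered
// channel-major, then kernel column offset, then kernel row offset —
// the R-side weight matrices use the same ordering.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_pad(const NumericMatrix& A, int H, int W, int B, int C,
                         int k, int stride, int pad, int outH, int outW) {
  const int nrow = outH * outW * B;
  NumericMatrix cols(no_init(nrow, k * k * C));  // every cell is written below
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* a = &A(0, c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int j = (c * k + dx) * k + dy;
        double* out = &cols(0, j);
        for (int b = 0; b < B; ++b) {
          const double* ab = a + (R_xlen_t)HW * b;
          for (int ow = 0; ow < outW; ++ow) {
            const int x = ow * stride + dx - pad;
            double* o = out + (R_xlen_t)outH * (ow + (R_xlen_t)outW * b);
            if (x < 0 || x >= W) {
              for (int oh = 0; oh < outH; ++oh) o[oh] = 0.0;
            } else {
              const double* col = ab + (R_xlen_t)H * x;
              for (int oh = 0; oh < outH; ++oh) {
                const int y = oh * stride + dy - pad;
                o[oh] = (y < 0 || y >= H) ? 0.0 : col[y];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix col2im_pad(const NumericMatrix& dcols, int H, int W, int B,
                         int C, int k, int stride, int pad, int outH,
                         int outW) {
  NumericMatrix dX(H * W * B, C);
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* a = &dX(0, c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int j = (c * k + dx) * k + dy;
        const double* dc = &dcols(0, j);
        for (int b = 0; b < B; ++b) {
          double* ab = a + (R_xlen_t)HW * b;
          for (int ow = 0; ow < outW; ++ow) {
            const int x = ow * stride + dx - pad;
            if (x < 0 || x >= W) continue;
            const double* d = dc + (R_xlen_t)outH * (ow + (R_xlen_t)outW * b);
            double* col = ab + (R_xlen_t)H * x;
            for (int oh = 0; oh < outH; ++oh) {
              const int y = oh * stride + dy - pad;
              if (y >= 0 && y < H) col[y] += d[oh];
            }
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling, stride 2; odd trailing rows/columns are dropped.
// Returns the pooled activations and the 1-based winning row index into the
// input matrix (per output element and channel). Ties resolve to the
// earliest candidate in (h, w) scan order.
// [[Rcpp::export]]
List pool2_forward(const NumericMatrix& A, int H, int W, int B, int C) {
  const int oh = H / 2, ow = W / 2;
  const int nrow = oh * ow * B;
  NumericMatrix out(no_init(nrow, C));   // every cell is written below
  IntegerMatrix idx(no_init(nrow, C));
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* a = &A(0, c);
    for (int b = 0; b < B; ++b) {
      const double* ab = a + (R_xlen_t)HW * b;
      for (int x = 0; x < ow; ++x) {
        for (int y = 0; y < oh; ++y) {
          const int y0 = 2 * y, x0 = 2 * x;
          int best = y0 + H * x0;
          double bv = ab[best];
          const int cand[3] = {y0 + 1 + H * x0, y0 + H * (x0 + 1),
                               y0 + 1 + H * (x0 + 1)};
          for (int q = 0; q < 3; ++q) {
            if (ab[cand[q]] > bv) { bv = ab[cand[q]]; best = cand[q]; }
          }
          const R_xlen_t r = y + (R_xlen_t)oh * (x + (R_xlen_t)ow * b);
          out(r, c) = bv;
          idx(r, c) = best + HW * b + 1;  // 1-based row into A
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix pool2_backward(const NumericMatrix& dOut,
                             const IntegerMatrix& idx, int in_rows) {
  NumericMatrix dA(in_rows, dOut.ncol());
  for (int c = 0; c < dOut.ncol(); ++c) {
    for (int r = 0; r < dOut.nrow(); ++r) {
      dA(idx(r, c) - 1, c) += dOut(r, c);
    }
  }
  return dA;
}
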