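#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as dense matrices of size (H*W*N) x C where the
// row index is r = h + H*w + H*W*n (0-based): column-major over the spatial
// grid of each minibatch item, items stacked along the row dimension.
// The convolution kernels live in convnet.cpp; these are the pooling and
// pixel-shuffle gathers/scatters.

// 2x2 max pooling, stride 2. H and W must be even. Returns the pooled map
// and the 1-based row index of each selected input element (for backprop).
// [[Rcpp::export]]
List maxpool2_fwd(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int H2 = H / 2, W2 = W / 2;
  const int HW = H * W, HW2 = H2 * W2;
  NumericMatrix out(HW2 * N, C);
  IntegerMatrix idx(HW2 * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < W2; ++w) {
        for (int h = 0; h < H2; ++h) {
          const int r00 = HW * n + H * (2 * w) + 2 * h;
          int best = r00;
          double v = xc[r00];
          const int cand[3] = { r00 + 1, r00 + H, r00 + H + 1 };
          for (int j = 0; j < 3; ++j)
            if (xc[cand[j]] > v) { v = xc[cand[j]]; best = cand[j]; }
          const int ro = HW2 * n + H2 * w + h;
          out(ro, c) = v;
          idx(ro, c) = best + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Scatter pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericMatrix maxpool2_bwd(const NumericMatrix& dout, const IntegerMatrix& idx,
                           int nrow_in) {
  const int C = dout.ncol();
  NumericMatrix dx(nrow_in, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < dout.nrow(); ++i) {
      dx(idx(i, c) - 1, c) += dout(i, c);
    }
  }
  return dx;
}

// Rearrange a (H*W*N) x (4*Co) matrix into a ((2H)*(2W)*N) x Co matrix:
// column 4*co + q lands at spatial offset (dy, dx) = (q % 2, q / 2) of the
// 2x2 output cell. This realizes a 2x2 stride-2 transposed convolution as a
// plain matrix product followed by this shuffle.
// [[Rcpp::export]]
NumericMatrix depth2space2(const NumericMatrix& x, int H, int W, int N) {
  const int Co = x.ncol() / 4;
  const int HW = H * W;
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(H2 * W2 * N, Co);
  for (int co = 0; co < Co; ++co) {
    for (int q = 0; q < 4; ++q) {
      const int dy = q % 2, dx = q / 2;
      const double* src = &x(0, 4 * co + q);
      double* dst = &out(0, co);
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const double* s = src + HW * n + H * w;
          double* d = dst + H2 * W2 * n + H2 * (2 * w + dx) + dy;
          for (int h = 0; h < H; ++h) d[2 * h] = s[h];
        }
      }
    }
  }
  return out;
}

// Inverse gather of depth2space2 (used for the transposed-conv backward pass).
// [[Rcpp::export]]
NumericMatrix space2depth2(const NumericMatrix& x, int H, int W, int N) {
  // H, W refer to the coarse grid: x has (2H)*(2W)*N rows.
  const int Co = x.ncol();
  const int HW = H * W;
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(HW * N, 4 * Co);
  for (int co = 0; co < Co; ++co) {
    for (int q = 0; q < 4; ++q) {
      const int dy = q % 2, dx = q / 2;
      const double* src = &x(0, co);
      double* dst = &out(0, 4 * co + q);
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const double* s = src + H2 * W2 * n + H2 * (2 * w + dx) + dy;
          double* d = dst + HW * n + H * w;
          for (int h = 0; h < H; ++h) d[h] = s[2 * h];
        }
      }
    }
  }
  return out;
}
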