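#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fused convolution kernels. Feature maps are (H*W*N) x C matrices with
// row index r = h + H*w + H*W*n. The 3x3 same-padding convolution is
// computed per minibatch item: an im2col tile (H*W x 9C) is gathered and
// multiplied against the (9C x Co) weight matrix with BLAS, which keeps the
// working set near cache size instead of materializing the whole batch.

static void gather_tile(const arma::mat& x, arma::mat& cols,
                        int H, int W, int n) {
  const int C = x.n_cols;
  const int HW = H * W;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c) + HW * n;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        double* oc = cols.colptr(9 * c + (dy + 1) + 3 * (dx + 1));
        const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
        for (int w = w0; w < w1; ++w) {
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          const double* src = xc + H * (w + dx) + dy;
          double* dst = oc + H * w;
          for (int h = h0; h < h1; ++h) dst[h] = src[h];
        }
      }
    }
  }
}

static void scatter_tile(const arma::mat& dcols, arma::mat& dx,
                         int H, int W, int n) {
  const int C = dx.n_cols;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* oc = dx.colptr(c) + HW * n;
    for (int dxo = -1; dxo <= 1; ++dxo) {
      for (int dy = -1; dy <= 1; ++dy) {
        const double* sc = dcols.colptr(9 * c + (dy + 1) + 3 * (dxo + 1));
        const int w0 = std::max(0, -dxo), w1 = std::min(W, W - dxo);
        for (int w = w0; w < w1; ++w) {
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          double* dst = oc + H * (w + dxo) + dy;
          const double* src = sc + H * w;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const arma::mat& x, const arma::mat& Wm,
                        int H, int W, int N) {
  const int HW = H * W;
  arma::mat out(x.n_rows, Wm.n_cols);
  arma::mat cols(HW, 9 * x.n_cols);
  for (int n = 0; n < N; ++n) {
    gather_tile(x, cols, H, W, n);
    out.rows(HW * n, HW * (n + 1) - 1) = cols * Wm;
  }
  return out;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const arma::mat& x, const arma::mat& Wm,
                   const arma::mat& dout, int H, int W, int N) {
  const int HW = H * W;
  arma::mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::mat dx(x.n_rows, x.n_cols, arma::fill::zeros);
  arma::mat cols(HW, 9 * x.n_cols);
  for (int n = 0; n < N; ++n) {
    gather_tile(x, cols, H, W, n);
    arma::mat dn = dout.rows(HW * n, HW * (n + 1) - 1);
    dW += cols.t() * dn;
    arma::mat dcols = dn * Wm.t();
    scatter_tile(dcols, dx, H, W, n);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// Batch-norm forward over columns (channels). Returns the normalized map,
// the affine output and the per-channel statistics needed for backprop.
// [[Rcpp::export]]
List bn_fwd_cpp(const arma::mat& x, const arma::vec& g, const arma::vec& b,
                const arma::vec& mu, const arma::vec& inv) {
  const int n = x.n_rows, C = x.n_cols;
  arma::mat xhat(n, C), out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* hc = xhat.colptr(c);
    double* oc = out.colptr(c);
    const double m = mu[c], iv = inv[c], gg = g[c], bb = b[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * iv;
      hc[i] = h;
      oc[i] = h * gg + bb;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const arma::mat& xhat, const arma::vec& inv,
                const arma::vec& g, const arma::mat& dout) {
  const int n = xhat.n_rows, C = xhat.n_cols;
  arma::mat dx(n, C);
  arma::vec dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* hc = xhat.colptr(c);
    const double* dc = dout.colptr(c);
    double s1 = 0, s2 = 0, s3 = 0;
    for (int i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * hc[i];
    }
    db[c] = s1;
    dg[c] = s2;
    const double m1 = g[c] * s1 / n, m2 = g[c] * s2 / n, iv = inv[c],
                 gg = g[c];
    double* xc = dx.colptr(c);
    for (int i = 0; i < n; ++i)
      xc[i] = iv * (gg * dc[i] - m1 - hc[i] * m2);
    (void)s3;
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// Per-channel mean and (biased) variance.
// [[Rcpp::export]]
List col_moments_cpp(const arma::mat& x) {
  const int n = x.n_rows, C = x.n_cols;
  arma::vec mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double s = 0, ss = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; ss += xc[i] * xc[i]; }
    mu[c] = s / n;
    v[c] = ss / n - mu[c] * mu[c];
  }
  return List::create(_["mu"] = mu, _["v"] = v);
}

// [[Rcpp::export]]
arma::mat relu_cpp(const arma::mat& x) {
  arma::mat out = x;
  out.for_each([](double& v) { if (v < 0) v = 0; });
  return out;
}

// dout where pre > 0, else 0.
// [[Rcpp::export]]
arma::mat relu_grad_cpp(const arma::mat& pre, const arma::mat& dout) {
  arma::mat out(pre.n_rows, pre.n_cols);
  const double* p = pre.memptr();
  const double* d = dout.memptr();
  double* o = out.memptr();
  const size_t n = pre.n_elem;
  for (size_t i = 0; i < n; ++i) o[i] = p[i] > 0 ? d[i] : 0.0;
  return out;
}
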