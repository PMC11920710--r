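// Index-heavy primitives for the grid U-Net. Feature maps are stored as
// (B*H*W) x C matrices with row index ((b*H) + i)*W + j (row-major pixels,
// samples stacked); convolutions are then plain GEMMs on im2col patches.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3x3 zero-padded patch extraction: returns (B*H*W) x 9C, patch offset
// k = (di+1)*3 + (dj+1) occupying columns [k*C, (k+1)*C).
// [[Rcpp::export]]
arma::mat im2col3(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols;
  const arma::uword N = (arma::uword)B * H * W;
  arma::mat out(N, 9 * C, arma::fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int di = k / 3 - 1, dj = k % 3 - 1;
    const int jlo = std::max(0, -dj), jhi = std::min(W, W - dj);
    for (int c = 0; c < C; ++c) {
      const double* src = X.colptr(c);
      double* dst = out.colptr((arma::uword)k * C + c);
      for (int b = 0; b < B; ++b) {
        for (int i = 0; i < H; ++i) {
          const int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          const double* s = src + ((arma::uword)(b * H + ii)) * W + dj;
          double* d = dst + ((arma::uword)(b * H + i)) * W;
          for (int j = jlo; j < jhi; ++j) d[j] = s[j];
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter-add patch gradients back to the image
// [[Rcpp::export]]
arma::mat col2im3(const arma::mat& dP, int B, int H, int W, int C) {
  const arma::uword N = (arma::uword)B * H * W;
  arma::mat dX(N, C, arma::fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int di = k / 3 - 1, dj = k % 3 - 1;
    const int jlo = std::max(0, -dj), jhi = std::min(W, W - dj);
    for (int c = 0; c < C; ++c) {
      const double* src = dP.colptr((arma::uword)k * C + c);
      double* dst = dX.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int i = 0; i < H; ++i) {
          const int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          double* d = dst + ((arma::uword)(b * H + ii)) * W + dj;
          const double* s = src + ((arma::uword)(b * H + i)) * W;
          for (int j = jlo; j < jhi; ++j) d[j] += s[j];
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling, stride 2; argmax returns 0-based row indices into X
// [[Rcpp::export]]
List maxpool2(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols, H2 = H / 2, W2 = W / 2;
  const arma::uword M = (arma::uword)B * H2 * W2;
  arma::mat Y(M, C);
  arma::umat A(M, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* y = Y.colptr(c);
    arma::uword* a = A.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int p = 0; p < H2; ++p) {
        for (int q = 0; q < W2; ++q) {
          const arma::uword m = ((arma::uword)(b * H2 + p)) * W2 + q;
          const arma::uword n00 = ((arma::uword)(b * H + 2 * p)) * W + 2 * q;
          const arma::uword cand[4] = {n00, n00 + 1, n00 + (arma::uword)W,
                                       n00 + (arma::uword)W + 1};
          int best = 0;
          double bv = src[cand[0]];
          for (int t = 1; t < 4; ++t) {
            if (src[cand[t]] > bv) { bv = src[cand[t]]; best = t; }
          }
          y[m] = bv;
          a[m] = cand[best];
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd(const arma::mat& dY, const arma::umat& A, int N) {
  arma::mat dX(N, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const double* g = dY.colptr(c);
    const arma::uword* a = A.colptr(c);
    double* d = dX.colptr(c);
    for (arma::uword m = 0; m < dY.n_rows; ++m) d[a[m]] += g[m];
  }
  return dX;
}
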