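// Minimal convolution / pooling kernels for the density-regression net.
// Layout: images and feature maps are H x W x C cubes; convolution weights
// are (k*k*Cin) x Cout matrices (patch unrolled row-major over (di, dj, c)),
// stride 1, odd kernel, zero 'same' padding scaled by the dilation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// unroll x into a (H*W) x (k*k*Cin) patch matrix for dilation dil
static arma::mat im2col(const arma::cube& x, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  arma::mat M(H * W, k * k * Cin, arma::fill::zeros);
  int col = 0;
  for (int di = 0; di < k; ++di) {
    for (int dj = 0; dj < k; ++dj) {
      const int oi = di * dil - pad, oj = dj * dil - pad;
      for (int c = 0; c < Cin; ++c, ++col) {
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + oi;
            if (si < 0 || si >= H) continue;
            M(i + H * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& bias, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat M = im2col(x, k, dil);
  arma::mat Y = M * w;
  Y.each_row() += bias.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(Y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int pad = dil * (k - 1) / 2;
  arma::mat M = im2col(x, k, dil);
  arma::mat G(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    G.col(c) = arma::vectorise(gy.slice(c));
  arma::mat gw = M.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gM = G * w.t();           // (H*W) x (k*k*Cin)
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  int col = 0;
  for (int di = 0; di < k; ++di) {
    for (int dj = 0; dj < k; ++dj) {
      const int oi = di * dil - pad, oj = dj * dil - pad;
      for (int c = 0; c < Cin; ++c, ++col) {
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + oi;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gM(i + H * j, col);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".avgpool2_fwd_cpp")]]
arma::cube avgpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j + 1 < W; j += 2)
      for (int i = 0; i + 1 < H; i += 2)
        out(i / 2, j / 2, c) =
          0.25 * (x(i, j, c) + x(i + 1, j, c) + x(i, j + 1, c) + x(i + 1, j + 1, c));
  return out;
}

// [[Rcpp::export(name = ".avgpool2_bwd_cpp")]]
arma::cube avgpool2_bwd(const arma::cube& gy) {
  const int h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  arma::cube gx(2 * h, 2 * w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g;
        gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g;
        gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return gx;
}
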