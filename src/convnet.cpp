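// Minimal CNN primitives for pixelwise regression: stride-1 "same" conv via
// im2col + GEMM, 2x2 max pooling, 2x2 stride-2 transposed conv, and nearest-
// neighbour upsampling, each with its backward pass. Tensors are H x W x C
// arma::cubes (column-major, matching R arrays).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int xj = j + dx - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int xi = i + dy - pad;
            if (xi < 0 || xi >= H) continue;
            col(r, j * H + i) = x(xi, xj, c);
          }
        }
      }
  return col;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_rows;
  const int pad = k / 2;
  arma::mat col = im2col(x, k, pad);
  arma::mat O = W * col;          // Cout x HW
  O.each_col() += b;
  arma::cube y(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    y.slice(co) = arma::reshape(O.row(co), H, Wd);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& W, int k,
                    const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows;
  const int pad = k / 2;
  arma::mat G(Cout, H * Wd);
  for (int co = 0; co < Cout; ++co)
    G.row(co) = arma::vectorise(gout.slice(co)).t();
  arma::mat col = im2col(x, k, pad);
  arma::mat gW = G * col.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat gcol = W.t() * G;     // Cin*k*k x HW
  arma::cube gx(H, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int j = 0; j < Wd; ++j) {
          const int xj = j + dx - pad;
          if (xj < 0 || xj >= Wd) continue;
          for (int i = 0; i < H; ++i) {
            const int xi = i + dy - pad;
            if (xi < 0 || xi >= H) continue;
            gx(xi, xj, c) += gcol(r, j * H + i);
          }
        }
      }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx[c * Ho * Wo + j * Ho + i] = c * H * W + bj * H + bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const IntegerVector& idx, const arma::cube& gout,
                            int H, int W) {
  const int C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gout.memptr();
  double* gp = gx.memptr();
  for (int q = 0; q < (int)gout.n_elem; ++q) gp[idx[q]] += g[q];
  return gx;
}

// W: Cout x (Cin*4), the 4 taps ordered (di,dj) = (0,0),(1,0),(0,1),(1,1).
// [[Rcpp::export]]
arma::cube upconv2_fwd_cpp(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows;
  arma::cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double w00 = W(co, ci * 4 + 0), w10 = W(co, ci * 4 + 1);
      const double w01 = W(co, ci * 4 + 2), w11 = W(co, ci * 4 + 3);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = x(i, j, ci);
          y(2 * i, 2 * j, co)         += v * w00;
          y(2 * i + 1, 2 * j, co)     += v * w10;
          y(2 * i, 2 * j + 1, co)     += v * w01;
          y(2 * i + 1, 2 * j + 1, co) += v * w11;
        }
    }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd_cpp(const arma::cube& x, const arma::mat& W,
                     const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows;
  arma::cube gx(H, Wd, Cin, arma::fill::zeros);
  arma::mat gW(arma::size(W), arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co)
    gb(co) = arma::accu(gout.slice(co));
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      double a00 = 0, a10 = 0, a01 = 0, a11 = 0;
      const double w00 = W(co, ci * 4 + 0), w10 = W(co, ci * 4 + 1);
      const double w01 = W(co, ci * 4 + 2), w11 = W(co, ci * 4 + 3);
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = x(i, j, ci);
          const double g00 = gout(2 * i, 2 * j, co);
          const double g10 = gout(2 * i + 1, 2 * j, co);
          const double g01 = gout(2 * i, 2 * j + 1, co);
          const double g11 = gout(2 * i + 1, 2 * j + 1, co);
          a00 += v * g00; a10 += v * g10; a01 += v * g01; a11 += v * g11;
          gx(i, j, ci) += g00 * w00 + g10 * w10 + g01 * w01 + g11 * w11;
        }
      gW(co, ci * 4 + 0) = a00; gW(co, ci * 4 + 1) = a10;
      gW(co, ci * 4 + 2) = a01; gW(co, ci * 4 + 3) = a11;
    }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
arma::cube upsample_nn_cpp(const arma::cube& x, int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H * f, W * f, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W * f; ++j)
      for (int i = 0; i < H * f; ++i)
        y(i, j, c) = x(i / f, j / f, c);
  return y;
}

// [[Rcpp::export]]
arma::cube upsample_nn_bwd_cpp(const arma::cube& gout, int f, int H, int W) {
  const int C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)gout.n_cols; ++j)
      for (int i = 0; i < (int)gout.n_rows; ++i)
        gx(i / f, j / f, c) += gout(i, j, c);
  return gx;
}
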