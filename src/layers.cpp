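// Minimal convolutional-network kernels used by the U-Net implementation.
// Activations are passed as cubes [H, W, C*B] (an R array [H, W, C, B] has
// identical memory layout), weights as matrices [C_out, K*K*C_in] with row
// index r = c*K*K + kx*K + ky (column offset kx, row offset ky).
// Convolutions use zero ("same") padding and stride 1.
//
// im2col is kept in transposed layout [H*W, K*K*C_in] so every write/read is
// a contiguous column, and all heavy lifting is a single GEMM per batch item.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_t(const cube& x, int b, int cin, int K, mat& colsT) {
  const int H = x.n_rows, W = x.n_cols;
  const int pad = (K - 1) / 2;
  for (int c = 0; c < cin; ++c) {
    const mat& sl = x.slice(b * cin + c);
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        const int r = c * K * K + kx * K + ky;
        const int dy = ky - pad, dx = kx - pad;
        const int lo_h = std::max(0, -dy), hi_h = std::min(H, H - dy);
        const int lo_w = std::max(0, -dx), hi_w = std::min(W, W - dx);
        mat view(colsT.colptr(r), H, W, false, true);
        if (K > 1) view.zeros();
        if (hi_h > lo_h && hi_w > lo_w) {
          view.submat(lo_h, lo_w, hi_h - 1, hi_w - 1) =
            sl.submat(lo_h + dy, lo_w + dx, hi_h - 1 + dy, hi_w - 1 + dx);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fw")]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& w, int n_batch,
                       int K) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices / n_batch;
  const int cout = w.n_rows;
  cube y(H, W, cout * n_batch);
  mat colsT(H * W, K * K * cin);
  const mat wt = w.t();
  for (int b = 0; b < n_batch; ++b) {
    im2col_t(x, b, cin, K, colsT);
    mat out(y.slice_memptr(b * cout), H * W, cout, false, true);
    out = colsT * wt;  // [H*W, cout] written straight into y's slices
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bw")]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& w,
                       const arma::cube& gy, int n_batch, int K) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices / n_batch;
  const int cout = w.n_rows;
  const int pad = (K - 1) / 2;
  cube gx(H, W, cin * n_batch, fill::zeros);
  mat gw(cout, K * K * cin, fill::zeros);
  mat colsT(H * W, K * K * cin);
  for (int b = 0; b < n_batch; ++b) {
    im2col_t(x, b, cin, K, colsT);
    const mat g(const_cast<double*>(gy.slice_memptr(b * cout)), H * W, cout,
                false, true);
    gw += g.t() * colsT;
    mat gcolsT = g * w;  // [H*W, K*K*cin]
    for (int c = 0; c < cin; ++c) {
      mat& gsl = gx.slice(b * cin + c);
      for (int kx = 0; kx < K; ++kx) {
        for (int ky = 0; ky < K; ++ky) {
          const int r = c * K * K + kx * K + ky;
          const int dy = ky - pad, dx = kx - pad;
          const int lo_h = std::max(0, -dy), hi_h = std::min(H, H - dy);
          const int lo_w = std::max(0, -dx), hi_w = std::min(W, W - dx);
          if (hi_h <= lo_h || hi_w <= lo_w) continue;
          const mat gview(const_cast<double*>(gcolsT.colptr(r)), H, W, false,
                          true);
          gsl.submat(lo_h + dy, lo_w + dx, hi_h - 1 + dy, hi_w - 1 + dx) +=
            gview.submat(lo_h, lo_w, hi_h - 1, hi_w - 1);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw);
}

// 2x2 max pooling, stride 2; ties resolved to the first element in fixed
// scan order. idx stores the linear index of the argmax within each input
// slice for the backward pass.
// [[Rcpp::export(name = ".cpp_pool_fw")]]
Rcpp::List cpp_pool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, S);
  ucube idx(Ho, Wo, S);
  for (int s = 0; s < S; ++s) {
    const mat& sl = x.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = sl(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        if (sl(2 * i + 1, 2 * j) > best) { best = sl(2 * i + 1, 2 * j); bi = 2 * i + 1; bj = 2 * j; }
        if (sl(2 * i, 2 * j + 1) > best) { best = sl(2 * i, 2 * j + 1); bi = 2 * i; bj = 2 * j + 1; }
        if (sl(2 * i + 1, 2 * j + 1) > best) { best = sl(2 * i + 1, 2 * j + 1); bi = 2 * i + 1; bj = 2 * j + 1; }
        y(i, j, s) = best;
        idx(i, j, s) = (uword)(bj * H + bi);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_pool_bw")]]
arma::cube cpp_pool_bw(const arma::cube& gy, const arma::ucube& idx, int H,
                       int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, S = gy.n_slices;
  cube gx(H, W, S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    mat& gsl = gx.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        gsl(idx(i, j, s)) += gy(i, j, s);
      }
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".cpp_up_fw")]]
arma::cube cpp_up_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  cube y(2 * H, 2 * W, S);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, s);
        y(2 * i, 2 * j, s) = v;
        y(2 * i + 1, 2 * j, s) = v;
        y(2 * i, 2 * j + 1, s) = v;
        y(2 * i + 1, 2 * j + 1, s) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_up_bw")]]
arma::cube cpp_up_bw(const arma::cube& gy) {
  const int Ho = gy.n_rows / 2, Wo = gy.n_cols / 2, S = gy.n_slices;
  cube gx(Ho, Wo, S);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        gx(i, j, s) = gy(2 * i, 2 * j, s) + gy(2 * i + 1, 2 * j, s) +
                      gy(2 * i, 2 * j + 1, s) + gy(2 * i + 1, 2 * j + 1, s);
      }
    }
  }
  return gx;
}

// Per-column affine helpers for batch normalization: columns of m are
// (channel, batch) planes; a and b are per-column coefficients.
// [[Rcpp::export(name = ".cpp_colscale")]]
arma::mat cpp_colscale(const arma::mat& m, const arma::vec& a,
                       const arma::vec& b) {
  mat y(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j) {
    y.col(j) = m.col(j) * a(j) + b(j);
  }
  return y;
}

// m1 * a1[col] + m2 * a2[col] + b[col]
// [[Rcpp::export(name = ".cpp_colscale2")]]
arma::mat cpp_colscale2(const arma::mat& m1, const arma::vec& a1,
                        const arma::mat& m2, const arma::vec& a2,
                        const arma::vec& b) {
  mat y(m1.n_rows, m1.n_cols);
  for (uword j = 0; j < m1.n_cols; ++j) {
    y.col(j) = m1.col(j) * a1(j) + m2.col(j) * a2(j) + b(j);
  }
  return y;
}
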