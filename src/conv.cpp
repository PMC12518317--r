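// Grouped 2-D convolution via im2col + BLAS, forward and backward.
// Feature maps are H x W x C x N arrays (column-major, height fastest);
// weights are k x k x (C_in/groups) x C_out.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int sz, int k, int stride, int pad) {
  return (sz + 2 * pad - k) / stride + 1;
}

// Fill A (Cg*k*k x Hout*Wout) with patches of one image's channel block.
static void im2col_block(const double* x, int H, int W,
                         int c0, int Cg, int k, int stride, int pad,
                         int Hout, int Wout, arma::mat& A) {
  const int HW = H * W;
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * HW;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * ci;
        for (int wo = 0; wo < Wout; ++wo) {
          const int w_in = wo * stride - pad + j;
          double* Acol = A.memptr() + (size_t)r + (size_t)A.n_rows * (size_t)(Hout * wo);
          if (w_in < 0 || w_in >= W) {
            for (int ho = 0; ho < Hout; ++ho) Acol[(size_t)A.n_rows * ho] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)W * 0 + (size_t)w_in * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int h_in = ho * stride - pad + i;
            Acol[(size_t)A.n_rows * ho] =
              (h_in < 0 || h_in >= H) ? 0.0 : xcol[h_in];
          }
        }
      }
    }
  }
}

// Scatter-add dA (Cg*k*k x Hout*Wout) back into one image's channel block.
static void col2im_block(const arma::mat& dA, double* dx, int H, int W,
                         int c0, int Cg, int k, int stride, int pad,
                         int Hout, int Wout) {
  const int HW = H * W;
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = dx + (size_t)(c0 + ci) * HW;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * ci;
        for (int wo = 0; wo < Wout; ++wo) {
          const int w_in = wo * stride - pad + j;
          if (w_in < 0 || w_in >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            const int h_in = ho * stride - pad + i;
            if (h_in < 0 || h_in >= H) continue;
            xc[h_in + (size_t)H * w_in] += dA((size_t)r, (size_t)(ho + Hout * wo));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: input channels %d != %d * groups", C, Cg);
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  const int Cout_g = Cout / groups;
  const int Hout = conv_out(H, k, stride, pad);
  const int Wout = conv_out(W, k, stride, pad);
  if (Hout < 1 || Wout < 1) stop("conv2d: output size would be empty");
  const int HWo = Hout * Wout;

  NumericVector y((size_t)HWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat A(Cg * k * k, HWo);
  const bool has_b = bias.isNotNull();
  NumericVector b;
  if (has_b) b = bias.get();

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)HWo * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col_block(xn, H, W, g * Cg, Cg, k, stride, pad, Hout, Wout, A);
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * Cg * (g * Cout_g),
                   k * k * Cg, Cout_g, false, true);
      arma::mat Y = A.t() * Wg;  // HWo x Cout_g, matches y layout
      std::memcpy(yn + (size_t)HWo * (g * Cout_g), Y.memptr(),
                  sizeof(double) * (size_t)HWo * Cout_g);
    }
    if (has_b)
      for (int c = 0; c < Cout; ++c) {
        double* yc = yn + (size_t)HWo * c;
        const double bc = b[c];
        for (int p = 0; p < HWo; ++p) yc[p] += bc;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    bool has_bias, int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cg = wd[2], Cout = wd[3];
  const int Hout = od[0], Wout = od[1];
  const int Cout_g = Cout / groups;
  const int HWo = Hout * Wout;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * Cg * Cout);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);

  arma::mat A(Cg * k * k, HWo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    const double* don = dout.begin() + (size_t)HWo * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col_block(xn, H, W, g * Cg, Cg, k, stride, pad, Hout, Wout, A);
      arma::mat dY(const_cast<double*>(don) + (size_t)HWo * (g * Cout_g),
                   HWo, Cout_g, false, true);
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * Cg * (g * Cout_g),
                   k * k * Cg, Cout_g, false, true);
      arma::mat dWg(dw.begin() + (size_t)k * k * Cg * (g * Cout_g),
                    k * k * Cg, Cout_g, false, true);
      dWg += A * dY;
      arma::mat dA = Wg * dY.t();  // CKK x HWo
      col2im_block(dA, dxn, H, W, g * Cg, Cg, k, stride, pad, Hout, Wout);
    }
    if (has_bias)
      for (int c = 0; c < Cout; ++c) {
        const double* dc = don + (size_t)HWo * c;
        double s = 0.0;
        for (int p = 0; p < HWo; ++p) s += dc[p];
        db[c] += s;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
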