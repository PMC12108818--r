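// Grouped 2-D convolution (cross-correlation) forward/backward via im2col.
//
// Tensor layout everywhere: column-major R arrays
//   x : (H, W, C, N)          feature maps, H fastest
//   w : (kh, kw, Cin/g, Cout) kernels
//   y : (Ho, Wo, Cout, N)
// The im2col buffer has one column per output position (ho fastest), rows
// ordered (kh, kw, cin_g) to match the flattened kernel, so each group is a
// single GEMM against the OpenBLAS R links to.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int Cg, int c0,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*Cg) x (Ho*Wo); x points at one sample, c0 = first channel
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + (size_t)(c0 + c) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          double* dst = col.colptr(0) + row; // strided writes below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + Ho * wo) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            col(row, ho + Ho * wo) =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, double* dx, int H, int W,
                       int Cg, int c0, int kh, int kw, int stride, int pad,
                       int Ho, int Wo) {
  for (int c = 0; c < Cg; ++c) {
    double* xc = dx + (size_t)(c0 + c) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H)
              xcol[hi] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("channel/group mismatch");
  int Coutg = Cout / groups;
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("non-positive output size");

  NumericVector y(Ho * (size_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cg, Cout,
                     false, true);
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = as<arma::vec>(bias.get());

  // pointwise fast path: each sample is a plain (HW x C) GEMM
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat Xn(const_cast<double*>(x.begin()) +
                             (size_t)n * H * W * C,
                         H * W, C, false, true);
      arma::mat Yn(y.begin() + (size_t)n * H * W * Cout, H * W, Cout,
                   false, true);
      Yn = Xn * Wm;
      if (has_b)
        for (int c = 0; c < Cout; ++c) Yn.col(c) += b(c);
    }
    return y;
  }

  arma::mat col(kh * kw * Cg, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cg, g * Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat Yg(yn + (size_t)g * Coutg * Ho * Wo, Ho * Wo, Coutg,
                   false, true);
      Yg = col.t() * Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
      if (has_b)
        for (int c = 0; c < Coutg; ++c)
          Yg.col(c) += b(g * Coutg + c);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int groups, bool need_dx,
                    bool need_db) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Coutg = Cout / groups;
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kh * kw * Cg, Cout, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cg, Cout,
                     false, true);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  NumericVector db(need_db ? Cout : 0);

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat Xn(const_cast<double*>(x.begin()) +
                             (size_t)n * H * W * C,
                         H * W, C, false, true);
      const arma::mat Dn(const_cast<double*>(dy.begin()) +
                             (size_t)n * Ho * Wo * Cout,
                         Ho * Wo, Cout, false, true);
      dWm += Xn.t() * Dn;
      if (need_db)
        for (int c = 0; c < Cout; ++c) db[c] += arma::accu(Dn.col(c));
      if (need_dx) {
        arma::mat dXn(dx.begin() + (size_t)n * H * W * C, H * W, C,
                      false, true);
        dXn = Dn * Wm.t();
      }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  arma::mat col(kh * kw * Cg, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cg, g * Cg, kh, kw, stride, pad, Ho, Wo, col);
      const arma::mat Dg(const_cast<double*>(dyn) +
                             (size_t)g * Coutg * Ho * Wo,
                         Ho * Wo, Coutg, false, true);
      dWm.cols(g * Coutg, (g + 1) * Coutg - 1) += col * Dg;
      if (need_db)
        for (int c = 0; c < Coutg; ++c)
          db[g * Coutg + c] += arma::accu(Dg.col(c));
      if (need_dx) {
        arma::mat dcol =
            Wm.cols(g * Coutg, (g + 1) * Coutg - 1) * Dg.t();
        col2im_acc(dcol, dx.begin() + (size_t)n * H * W * C, H, W, Cg,
                   g * Cg, kh, kw, stride, pad, Ho, Wo);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
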