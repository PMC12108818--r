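// Fused elementwise/reduction kernels for the training loop hot path:
// batch normalization, SiLU / Hard-Swish activations, and a direct
// depthwise convolution stencil. Layouts match conv.cpp: (H, W, C, N).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// ---- batch norm ---------------------------------------------------------

// [[Rcpp::export]]
List bn_fwd_train_cpp(NumericVector x, NumericVector gamma,
                      NumericVector beta, double eps) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  double m = (double)hw * N;
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; var[c] += s2;
    }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = var[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = d; y.attr("dim") = d;
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double* ph = xhat.begin() + n * cs + c * hw;
      double* py = y.begin() + n * cs + c * hw;
      double mc = mu[c], ic = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        double xh = (p[i] - mc) * ic;
        ph[i] = xh;
        py[i] = g * xh + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector bn_fwd_eval_cpp(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double* py = y.begin() + n * cs + c * hw;
      double sc = scale[c], sh = shift[c];
      for (size_t i = 0; i < hw; ++i) py[i] = sc * p[i] + sh;
    }
  return y;
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector invstd) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dy.begin() + n * cs + c * hw;
      const double* ph = xhat.begin() + n * cs + c * hw;
      double s = 0, sx = 0;
      for (size_t i = 0; i < hw; ++i) { s += pd[i]; sx += pd[i] * ph[i]; }
      dbeta[c] += s; dgamma[c] += sx;
    }
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dy.begin() + n * cs + c * hw;
      const double* ph = xhat.begin() + n * cs + c * hw;
      double* px = dx.begin() + n * cs + c * hw;
      double g = gamma[c], ic = invstd[c];
      double s1 = dbeta[c] / m * g, s2 = dgamma[c] / m * g;
      for (size_t i = 0; i < hw; ++i)
        px[i] = (g * pd[i] - s1 - ph[i] * s2) * ic;
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- activations --------------------------------------------------------
// type: 1 = silu, 2 = hard_sigmoid, 3 = hard_swish

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
NumericVector act_fwd_cpp(NumericVector x, int type) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  R_xlen_t n = x.size();
  if (type == 1)
    for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] * sigm(x[i]);
  else if (type == 2)
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = (x[i] + 3.0) / 6.0;
      y[i] = v < 0 ? 0 : (v > 1 ? 1 : v);
    }
  else
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = (x[i] + 3.0) / 6.0;
      v = v < 0 ? 0 : (v > 1 ? 1 : v);
      y[i] = x[i] * v;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector act_bwd_cpp(NumericVector x, NumericVector dy, int type) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  R_xlen_t n = x.size();
  if (type == 1)
    for (R_xlen_t i = 0; i < n; ++i) {
      double s = sigm(x[i]);
      dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
    }
  else if (type == 2)
    for (R_xlen_t i = 0; i < n; ++i)
      dx[i] = (x[i] > -3.0 && x[i] < 3.0) ? dy[i] / 6.0 : 0.0;
  else
    for (R_xlen_t i = 0; i < n; ++i) {
      double g;
      if (x[i] <= -3.0) g = 0.0;
      else if (x[i] >= 3.0) g = 1.0;
      else g = (x[i] + 3.0) / 6.0 + x[i] / 6.0;
      dx[i] = dy[i] * g;
    }
  return dx;
}

// ---- depthwise convolution ---------------------------------------------

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias, int stride,
                             int pad) {
  IntegerVector d = x.attr("dim"), wd = w.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int kh = wd[0], kw = wd[1];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  bool has_b = bias.isNotNull();
  NumericVector b;
  if (has_b) b = bias.get();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * H * W;
      const double* pw = w.begin() + (size_t)c * kh * kw;
      double* py = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      double bc = has_b ? b[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = bc;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int j = 0; j < kw; ++j) {
            int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              s += px[hi + (size_t)wi * H] * pw[i + kh * j];
            }
          }
          py[ho + (size_t)wo * Ho] = s;
        }
    }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_db) {
  IntegerVector d = x.attr("dim"), wd = w.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int kh = wd[0], kw = wd[1];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = d; dw.attr("dim") = wd;
  NumericVector db(need_db ? C : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * H * W;
      const double* pd = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* pdx = dx.begin() + ((size_t)n * C + c) * H * W;
      double* pdw = dw.begin() + (size_t)c * kh * kw;
      const double* pw = w.begin() + (size_t)c * kh * kw;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = pd[ho + (size_t)wo * Ho];
          if (g == 0.0) continue;
          if (need_db) db[c] += g;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int j = 0; j < kw; ++j) {
            int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              pdw[i + kh * j] += px[hi + (size_t)wi * H] * g;
              pdx[hi + (size_t)wi * H] += pw[i + kh * j] * g;
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- fused batch norm + activation -------------------------------------
// act: 0 = none, 1 = silu, 3 = hard_swish (codes as in act_fwd_cpp)

static inline double act_apply(double z, int act) {
  if (act == 1) return z * sigm(z);
  if (act == 3) {
    double v = (z + 3.0) / 6.0;
    v = v < 0 ? 0 : (v > 1 ? 1 : v);
    return z * v;
  }
  return z;
}

static inline double act_grad(double z, int act) {
  if (act == 1) {
    double s = sigm(z);
    return s * (1.0 + z * (1.0 - s));
  }
  if (act == 3) {
    if (z <= -3.0) return 0.0;
    if (z >= 3.0) return 1.0;
    return (z + 3.0) / 6.0 + z / 6.0;
  }
  return 1.0;
}

// [[Rcpp::export]]
List bnact_fwd_train_cpp(NumericVector x, NumericVector gamma,
                         NumericVector beta, double eps, int act) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  double m = (double)hw * N;
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; var[c] += s2;
    }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = var[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = d; y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double* ph = xhat.begin() + n * cs + c * hw;
      double* py = y.begin() + n * cs + c * hw;
      double mc = mu[c], ic = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        double xh = (p[i] - mc) * ic;
        ph[i] = xh;
        py[i] = act_apply(g * xh + b, act);
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector bnact_fwd_eval_cpp(NumericVector x, NumericVector scale,
                                 NumericVector shift, int act) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * cs + c * hw;
      double* py = y.begin() + n * cs + c * hw;
      double sc = scale[c], sh = shift[c];
      for (size_t i = 0; i < hw; ++i) py[i] = act_apply(sc * p[i] + sh, act);
    }
  return y;
}

// [[Rcpp::export]]
List bnact_bwd_cpp(NumericVector dy, NumericVector xhat,
                   NumericVector gamma, NumericVector beta,
                   NumericVector invstd, int act) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W, cs = hw * C;
  double m = (double)hw * N;
  // first pass: dz = dy * act'(z) with z = gamma*xhat + beta, plus sums
  NumericVector dz(dy.size());
  dz.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dy.begin() + n * cs + c * hw;
      const double* ph = xhat.begin() + n * cs + c * hw;
      double* pz = dz.begin() + n * cs + c * hw;
      double g = gamma[c], b = beta[c];
      double s = 0, sx = 0;
      for (size_t i = 0; i < hw; ++i) {
        double z = g * ph[i] + b;
        double v = pd[i] * act_grad(z, act);
        pz[i] = v;
        s += v; sx += v * ph[i];
      }
      dbeta[c] += s; dgamma[c] += sx;
    }
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pz = dz.begin() + n * cs + c * hw;
      const double* ph = xhat.begin() + n * cs + c * hw;
      double* px = dx.begin() + n * cs + c * hw;
      double g = gamma[c], ic = invstd[c];
      double s1 = dbeta[c] / m * g, s2 = dgamma[c] / m * g;
      for (size_t i = 0; i < hw; ++i)
        px[i] = (g * pz[i] - s1 - ph[i] * s2) * ic;
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
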