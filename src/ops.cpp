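// Low-level NCHW tensor kernels. Arrays arrive from R with dim c(H, W, C, N)
// (column-major, H fastest); convolution weights with dim c(kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// im2col for one sample: returns (kh*kw*C) x (OH*OW)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int p, int d,
                   int OH, int OW, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * s - p + j * d;
          double* dst = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)ow * OH;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[(size_t)col.n_rows * oh] = 0.0;
          } else {
            const double* src = xc + (size_t)wi * H;
            for (int oh = 0; oh < OH; ++oh) {
              int hi = oh * s - p + i * d;
              dst[(size_t)col.n_rows * oh] =
                (hi < 0 || hi >= H) ? 0.0 : src[hi];
            }
          }
        }
      }
    }
  }
}

// col2im accumulation (adjoint of im2col)
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int s, int p, int d,
                   int OH, int OW, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * s - p + j * d;
          if (wi < 0 || wi >= W) continue;
          const double* src = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)ow * OH;
          double* dstc = xc + (size_t)wi * H;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * s - p + i * d;
            if (hi >= 0 && hi < H) dstc[hi] += src[(size_t)col.n_rows * oh];
          }
        }
      }
    }
  }
}

// single-precision im2col for one sample
static void im2col_f(const float* x, int H, int W, int C,
                     int kh, int kw, int s, int p, int d,
                     int OH, int OW, arma::fmat& col) {
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * s - p + j * d;
          float* dst = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)ow * OH;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[(size_t)col.n_rows * oh] = 0.0f;
          } else {
            const float* src = xc + (size_t)wi * H;
            for (int oh = 0; oh < OH; ++oh) {
              int hi = oh * s - p + i * d;
              dst[(size_t)col.n_rows * oh] = (hi < 0 || hi >= H) ? 0.0f : src[hi];
            }
          }
        }
      }
    }
  }
}

static void col2im_f(const arma::fmat& col, int H, int W, int C,
                     int kh, int kw, int s, int p, int d,
                     int OH, int OW, float* gx) {
  for (int c = 0; c < C; ++c) {
    float* xc = gx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * s - p + j * d;
          if (wi < 0 || wi >= W) continue;
          const float* src = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)ow * OH;
          float* dstc = xc + (size_t)wi * H;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * s - p + i * d;
            if (hi >= 0 && hi < H) dstc[hi] += src[(size_t)col.n_rows * oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_f(NumericVector x, IntegerVector xd,
                           NumericVector w, IntegerVector wd,
                           Nullable<NumericVector> bias,
                           int stride, int pad, int dil) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: channel mismatch");
  int OH = out_dim(H, kh, stride, pad, dil), OW = out_dim(W, kw, stride, pad, dil);
  NumericVector y((size_t)OH * OW * Co * N);
  size_t HW = (size_t)H * W;
  arma::fvec xf(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) xf[i] = (float)x[i];
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    arma::fmat Wf(C, Co);
    for (size_t i = 0; i < (size_t)C * Co; ++i) Wf[i] = (float)w[i];
    for (int n = 0; n < N; ++n) {
      arma::fmat X(xf.memptr() + HW * C * n, HW, C, false, true);
      arma::fmat Y = X * Wf;
      double* yp = y.begin() + HW * Co * n;
      if (bias.isNotNull()) {
        NumericVector bv(bias);
        for (int co = 0; co < Co; ++co)
          for (size_t q = 0; q < HW; ++q) yp[q + HW * co] = Y(q, co) + bv[co];
      } else {
        for (size_t i = 0; i < HW * Co; ++i) yp[i] = Y[i];
      }
    }
    y.attr("dim") = IntegerVector::create(OH, OW, Co, N);
    return y;
  }
  size_t K = (size_t)kh * kw * Ci;
  arma::fmat Wm(Co, K);
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < K; ++k) Wm(co, k) = (float)w[k + K * co];
  arma::fmat col(K, (size_t)OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col_f(xf.memptr() + HW * C * n, H, W, C, kh, kw, stride, pad, dil, OH, OW, col);
    arma::fmat out = Wm * col;
    double* yp = y.begin() + (size_t)OH * OW * Co * n;
    for (int co = 0; co < Co; ++co) {
      double b = 0.0;
      if (bias.isNotNull()) b = NumericVector(bias)[co];
      for (size_t q = 0; q < (size_t)OH * OW; ++q)
        yp[q + (size_t)OH * OW * co] = out(co, q) + b;
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw_f(NumericVector x, IntegerVector xd,
                     NumericVector w, IntegerVector wd,
                     NumericVector gy, bool need_gx, bool need_gb,
                     int stride, int pad, int dil) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int OH = out_dim(H, kh, stride, pad, dil), OW = out_dim(W, kw, stride, pad, dil);
  size_t HW = (size_t)H * W, OHW = (size_t)OH * OW, K = (size_t)kh * kw * Ci;
  arma::fvec xf(x.size()), gf(gy.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) xf[i] = (float)x[i];
  for (R_xlen_t i = 0; i < gy.size(); ++i) gf[i] = (float)gy[i];
  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  NumericVector gb(need_gb ? Co : 0);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    arma::fmat Wf(C, Co);
    for (size_t i = 0; i < (size_t)C * Co; ++i) Wf[i] = (float)w[i];
    arma::fmat gW(C, Co, arma::fill::zeros);
    arma::fvec gxa(need_gx ? (size_t)HW * C * N : 1, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      arma::fmat X(xf.memptr() + HW * C * n, HW, C, false, true);
      arma::fmat G(gf.memptr() + HW * Co * n, HW, Co, false, true);
      gW += X.t() * G;
      if (need_gb) for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.col(co));
      if (need_gx) {
        arma::fmat GX(gxa.memptr() + HW * C * n, HW, C, false, true);
        GX = G * Wf.t();
      }
    }
    NumericVector gw((size_t)Ci * Co);
    for (size_t i = 0; i < (size_t)Ci * Co; ++i) gw[i] = gW[i];
    gw.attr("dim") = IntegerVector::create(1, 1, Ci, Co);
    if (need_gx) {
      for (size_t i = 0; i < (size_t)HW * C * N; ++i) gx[i] = gxa[i];
      gx.attr("dim") = IntegerVector::create(H, W, C, N);
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::fmat Wm(Co, K);
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < K; ++k) Wm(co, k) = (float)w[k + K * co];
  arma::fmat gW(Co, K, arma::fill::zeros);
  arma::fvec gxa(need_gx ? (size_t)HW * C * N : 1, arma::fill::zeros);
  arma::fmat col(K, OHW), G(Co, OHW);
  for (int n = 0; n < N; ++n) {
    im2col_f(xf.memptr() + HW * C * n, H, W, C, kh, kw, stride, pad, dil, OH, OW, col);
    const float* gp = gf.memptr() + OHW * Co * n;
    for (int co = 0; co < Co; ++co)
      for (size_t q = 0; q < OHW; ++q) G(co, q) = gp[q + OHW * co];
    gW += G * col.t();
    if (need_gb)
      for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.row(co));
    if (need_gx) {
      arma::fmat gcol = Wm.t() * G;
      col2im_f(gcol, H, W, C, kh, kw, stride, pad, dil, OH, OW,
               gxa.memptr() + HW * C * n);
    }
  }
  NumericVector gw((size_t)kh * kw * Ci * Co);
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < K; ++k) gw[k + K * co] = gW(co, k);
  gw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  if (need_gx) {
    for (size_t i = 0; i < (size_t)HW * C * N; ++i) gx[i] = gxa[i];
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         Nullable<NumericVector> bias,
                         int stride, int pad, int dil) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: channel mismatch");
  int OH = out_dim(H, kh, stride, pad, dil), OW = out_dim(W, kw, stride, pad, dil);
  NumericVector y((size_t)OH * OW * Co * N);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    // pointwise convolution: per-sample GEMM without im2col
    size_t HW = (size_t)H * W;
    arma::mat Wm(const_cast<double*>(w.begin()), C, Co, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + HW * C * n, HW, C, false, true);
      arma::mat Y(y.begin() + HW * Co * n, HW, Co, false, true);
      Y = X * Wm;
      if (bias.isNotNull()) {
        NumericVector bv(bias);
        for (int co = 0; co < Co; ++co) Y.col(co) += bv[co];
      }
    }
    y.attr("dim") = IntegerVector::create(H, W, Co, N);
    return y;
  }
  // weight as (Co) x (kh*kw*Ci): element (i,j,ci,co) at row co, col i+kh*(j+kw*ci)
  arma::mat Wm(Co, (size_t)kh * kw * Ci);
  const double* wp = w.begin();
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < (size_t)kh * kw * Ci; ++k)
      Wm(co, k) = wp[k + (size_t)kh * kw * Ci * co];
  arma::mat col((size_t)kh * kw * Ci, (size_t)OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, dil, OH, OW, col);
    arma::mat out = Wm * col; // Co x (OH*OW)
    double* yp = y.begin() + (size_t)n * OH * OW * Co;
    for (int co = 0; co < Co; ++co) {
      double b = 0.0;
      if (bias.isNotNull()) b = NumericVector(bias)[co];
      for (size_t q = 0; q < (size_t)OH * OW; ++q)
        yp[q + (size_t)OH * OW * co] = out(co, q) + b;
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gy, bool need_gx, bool need_gb,
                   int stride, int pad, int dil) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int OH = out_dim(H, kh, stride, pad, dil), OW = out_dim(W, kw, stride, pad, dil);
  size_t K = (size_t)kh * kw * Ci;
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    size_t HW = (size_t)H * W;
    arma::mat Wm1(const_cast<double*>(w.begin()), C, Co, false, true);
    arma::mat gW1(C, Co, arma::fill::zeros);
    NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
    NumericVector gb(need_gb ? Co : 0);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + HW * C * n, HW, C, false, true);
      arma::mat G(const_cast<double*>(gy.begin()) + HW * Co * n, HW, Co, false, true);
      gW1 += X.t() * G;
      if (need_gb) for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.col(co));
      if (need_gx) {
        arma::mat GX(gx.begin() + HW * C * n, HW, C, false, true);
        GX = G * Wm1.t();
      }
    }
    NumericVector gw((size_t)Ci * Co);
    std::copy(gW1.memptr(), gW1.memptr() + (size_t)Ci * Co, gw.begin());
    gw.attr("dim") = IntegerVector::create(1, 1, Ci, Co);
    if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat Wm(Co, K);
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < K; ++k) Wm(co, k) = w[k + K * co];
  arma::mat gW(Co, K, arma::fill::zeros);
  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  NumericVector gb(need_gb ? Co : 0);
  arma::mat col(K, (size_t)OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, dil, OH, OW, col);
    arma::mat G(Co, (size_t)OH * OW);
    const double* gp = gy.begin() + (size_t)n * OH * OW * Co;
    for (int co = 0; co < Co; ++co)
      for (size_t q = 0; q < (size_t)OH * OW; ++q) G(co, q) = gp[q + (size_t)OH * OW * co];
    gW += G * col.t();
    if (need_gb)
      for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.row(co));
    if (need_gx) {
      arma::mat gcol = Wm.t() * G; // K x OH*OW
      col2im(gcol, H, W, C, kh, kw, stride, pad, dil, OH, OW,
             gx.begin() + (size_t)n * H * W * C);
    }
  }
  NumericVector gw((size_t)kh * kw * Ci * Co);
  for (int co = 0; co < Co; ++co)
    for (size_t k = 0; k < K; ++k) gw[k + K * co] = gW(co, k);
  gw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, IntegerVector xd, int k, int stride, int pad) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = out_dim(H, k, stride, pad, 1), OW = out_dim(W, k, stride, pad, 1);
  NumericVector y((size_t)OH * OW * C * N);
  IntegerVector idx((size_t)OH * OW * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = R_NegInf; int bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = ow * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = oh * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          }
          y[base + oh + (size_t)OH * ow] = best;
          idx[base + oh + (size_t)OH * ow] = bi;
        }
    }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector idx, IntegerVector xd) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector gx((size_t)H * W * C * N);
  size_t HW = (size_t)H * W, n_out = gy.size();
  size_t per = n_out / ((size_t)C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn)
    for (size_t q = 0; q < per; ++q) {
      int bi = idx[q + per * cn];
      if (bi >= 0) gx[bi + HW * cn] += gy[q + per * cn];
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest(NumericVector x, IntegerVector xd, int scale) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H * scale, OW = W * scale;
  NumericVector y((size_t)OH * OW * C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)OH * OW * cn;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        ys[oh + (size_t)OH * ow] = xs[(oh / scale) + (size_t)H * (ow / scale)];
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_bw(NumericVector gy, IntegerVector xd, int scale) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H * scale, OW = W * scale;
  NumericVector gx((size_t)H * W * C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gs = gy.begin() + (size_t)OH * OW * cn;
    double* xs = gx.begin() + (size_t)H * W * cn;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        xs[(oh / scale) + (size_t)H * (ow / scale)] += gs[oh + (size_t)OH * ow];
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// 5x5 average pool, stride 1, pad 2 ("same"), used by the SAC switch head
// [[Rcpp::export]]
NumericVector cpp_avgpool_same(NumericVector x, IntegerVector xd, int k) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int p = k / 2;
  NumericVector y((size_t)H * W * C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)H * W * cn;
    for (int w0 = 0; w0 < W; ++w0)
      for (int h0 = 0; h0 < H; ++h0) {
        double s = 0.0;
        for (int j = -p; j <= p; ++j) {
          int wi = w0 + j; if (wi < 0 || wi >= W) continue;
          for (int i = -p; i <= p; ++i) {
            int hi = h0 + i; if (hi < 0 || hi >= H) continue;
            s += xs[hi + (size_t)H * wi];
          }
        }
        ys[h0 + (size_t)H * w0] = s / (k * k);
      }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_same_bw(NumericVector gy, IntegerVector xd, int k) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int p = k / 2;
  NumericVector gx((size_t)H * W * C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gs = gy.begin() + (size_t)H * W * cn;
    double* xs = gx.begin() + (size_t)H * W * cn;
    for (int w0 = 0; w0 < W; ++w0)
      for (int h0 = 0; h0 < H; ++h0) {
        double g = gs[h0 + (size_t)H * w0] / (k * k);
        for (int j = -p; j <= p; ++j) {
          int wi = w0 + j; if (wi < 0 || wi >= W) continue;
          for (int i = -p; i <= p; ++i) {
            int hi = h0 + i; if (hi < 0 || hi >= H) continue;
            xs[hi + (size_t)H * wi] += g;
          }
        }
      }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// per-channel mean and mean-of-squares over (H, W, N)
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x, IntegerVector xd) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector mean(C), m2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + HW * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      mean[c] += s; m2[c] += s2;
    }
  double denom = (double)HW * N;
  for (int c = 0; c < C; ++c) { mean[c] /= denom; m2[c] /= denom; }
  return List::create(_["mean"] = mean, _["m2"] = m2);
}

// y = x * a[channel] + b[channel]
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, IntegerVector xd,
                              NumericVector a, NumericVector b) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + HW * (c + (size_t)C * n);
      double* ys = y.begin() + HW * (c + (size_t)C * n);
      double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) ys[i] = xs[i] * ac + bc;
    }
  y.attr("dim") = xd;
  return y;
}

// per-channel mean(g) and mean(g * h) in one pass
// [[Rcpp::export]]
List cpp_chan_stats2(NumericVector g, NumericVector h, IntegerVector xd) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector mg(C), mgh(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = HW * (c + (size_t)C * n);
      const double* gs = g.begin() + off;
      const double* hs = h.begin() + off;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) { s += gs[i]; s2 += gs[i] * hs[i]; }
      mg[c] += s; mgh[c] += s2;
    }
  double denom = (double)HW * N;
  for (int c = 0; c < C; ++c) { mg[c] /= denom; mgh[c] /= denom; }
  return List::create(_["mg"] = mg, _["mgh"] = mgh);
}

// general broadcast multiply: dims of b are 1 or equal to dims of x
// [[Rcpp::export]]
NumericVector cpp_bc_mul(NumericVector x, IntegerVector xd,
                         NumericVector b, IntegerVector bd) {
  int d0 = xd[0], d1 = xd[1], d2 = xd[2], d3 = xd[3];
  int s0 = bd[0] == 1 ? 0 : 1;
  int s1 = bd[1] == 1 ? 0 : bd[0];
  int s2 = bd[2] == 1 ? 0 : bd[0] * bd[1];
  int s3 = bd[3] == 1 ? 0 : bd[0] * bd[1] * bd[2];
  NumericVector y(x.size());
  size_t q = 0;
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t boff = (size_t)i1 * s1 + (size_t)i2 * s2 + (size_t)i3 * s3;
        if (s0 == 0) {
          double bv = b[boff];
          for (int i0 = 0; i0 < d0; ++i0, ++q) y[q] = x[q] * bv;
        } else {
          for (int i0 = 0; i0 < d0; ++i0, ++q) y[q] = x[q] * b[boff + i0];
        }
      }
  y.attr("dim") = xd;
  return y;
}

// sum x down to broadcast shape bd (adjoint of broadcast expansion)
// [[Rcpp::export]]
NumericVector cpp_bc_sum(NumericVector x, IntegerVector xd, IntegerVector bd) {
  int d0 = xd[0], d1 = xd[1], d2 = xd[2], d3 = xd[3];
  int s0 = bd[0] == 1 ? 0 : 1;
  int s1 = bd[1] == 1 ? 0 : bd[0];
  int s2 = bd[2] == 1 ? 0 : bd[0] * bd[1];
  int s3 = bd[3] == 1 ? 0 : bd[0] * bd[1] * bd[2];
  NumericVector y((size_t)bd[0] * bd[1] * bd[2] * bd[3]);
  size_t q = 0;
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t boff = (size_t)i1 * s1 + (size_t)i2 * s2 + (size_t)i3 * s3;
        if (s0 == 0) {
          double acc = 0;
          for (int i0 = 0; i0 < d0; ++i0, ++q) acc += x[q];
          y[boff] += acc;
        } else {
          for (int i0 = 0; i0 < d0; ++i0, ++q) y[boff + i0] += x[q];
        }
      }
  y.attr("dim") = bd;
  return y;
}

// concatenate 4D arrays along the channel dimension (dim 3)
// [[Rcpp::export]]
NumericVector cpp_concat_c(List xs, List dims) {
  int K = xs.size();
  int H = IntegerVector(dims[0])[0], W = IntegerVector(dims[0])[1];
  int N = IntegerVector(dims[0])[3];
  int Ctot = 0;
  for (int k = 0; k < K; ++k) Ctot += IntegerVector(dims[k])[2];
  size_t HW = (size_t)H * W;
  NumericVector y(HW * Ctot * N);
  for (int n = 0; n < N; ++n) {
    size_t coff = 0;
    for (int k = 0; k < K; ++k) {
      NumericVector xk = xs[k];
      int Ck = IntegerVector(dims[k])[2];
      std::copy(xk.begin() + HW * Ck * n, xk.begin() + HW * Ck * (n + 1),
                y.begin() + HW * (coff + (size_t)Ctot * n));
      coff += Ck;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  return y;
}

// contiguous channel slice [c0, c0+len) of a 4D array
// [[Rcpp::export]]
NumericVector cpp_slice_c(NumericVector x, IntegerVector xd, int c0, int len) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(HW * len * N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + HW * ((size_t)c0 + (size_t)C * n),
              x.begin() + HW * ((size_t)c0 + len + (size_t)C * n),
              y.begin() + HW * (size_t)len * n);
  y.attr("dim") = IntegerVector::create(H, W, len, N);
  return y;
}

// scatter-add a channel slice back (adjoint of cpp_slice_c)
// [[Rcpp::export]]
NumericVector cpp_slice_c_bw(NumericVector g, IntegerVector xd, int c0, int len) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    std::copy(g.begin() + HW * (size_t)len * n,
              g.begin() + HW * (size_t)len * (n + 1),
              y.begin() + HW * ((size_t)c0 + (size_t)C * n));
  y.attr("dim") = xd;
  return y;
}


// [[Rcpp::export]]
NumericVector cpp_silu(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_silu_bw(NumericVector x, NumericVector g) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = g[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  y.attr("dim") = x.attr("dim");
  return y;
}
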