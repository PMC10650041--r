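// Low-level numerical kernels for the network.
//
// Tensor layout convention (shared with the R side): a feature map is a
// numeric array with dim = c(H, W, C, N), column-major, so pixels within a
// channel are contiguous.  Convolution weights are stored with
// dim = c(KH, KW, Cin/groups, Cout); flattened column-major this matches the
// im2col row ordering exactly, so the GEMM needs no reshuffling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-D array", what);
  return d;
}

// im2col for one image and one channel group.
// col is (KH*KW*Cg) x (HO*WO); column j = ho + HO*wo, row = kh + KH*(kw+KW*cg).
// Traversal is column-major so both the writes (down a column) and the reads
// (down an input column) are contiguous.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// pad_mode: 0 = zero padding, 1 = replicate (edge) padding
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int KH, int KW, int stride, int pad, int pad_mode,
                   int HO, int WO, arma::mat& col) {
  const long planeHW = (long)H * W;
  const double* xg = x + (long)c0 * planeHW;
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      double* cj = col.colptr(ho + (long)HO * wo);
      const int hbase = ho * stride - pad;
      const int wbase = wo * stride - pad;
      for (int cg = 0; cg < Cg; ++cg) {
        const double* xc = xg + (long)cg * planeHW;
        for (int kw = 0; kw < KW; ++kw) {
          const int wi = wbase + kw;
          double* dst = cj + KH * (kw + (long)KW * cg);
          if ((wi < 0 || wi >= W) && pad_mode == 0) {
            for (int kh = 0; kh < KH; ++kh) dst[kh] = 0.0;
            continue;
          }
          const double* src = xc + (long)H * clampi(wi, 0, W - 1);
          for (int kh = 0; kh < KH; ++kh) {
            const int hi = hbase + kh;
            if (pad_mode == 0) dst[kh] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
            else dst[kh] = src[clampi(hi, 0, H - 1)];
          }
        }
      }
    }
  }
}

// scatter-add counterpart of im2col
static void col2im(const arma::mat& col, double* gx, int H, int W, int c0, int Cg,
                   int KH, int KW, int stride, int pad, int pad_mode,
                   int HO, int WO) {
  const long planeHW = (long)H * W;
  double* xg = gx + (long)c0 * planeHW;
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      const double* cj = col.colptr(ho + (long)HO * wo);
      const int hbase = ho * stride - pad;
      const int wbase = wo * stride - pad;
      for (int cg = 0; cg < Cg; ++cg) {
        double* xc = xg + (long)cg * planeHW;
        for (int kw = 0; kw < KW; ++kw) {
          const int wi = wbase + kw;
          if ((wi < 0 || wi >= W) && pad_mode == 0) continue;
          const double* src = cj + KH * (kw + (long)KW * cg);
          double* dst = xc + (long)H * clampi(wi, 0, W - 1);
          for (int kh = 0; kh < KH; ++kh) {
            const int hi = hbase + kh;
            if (pad_mode == 0) { if (hi >= 0 && hi < H) dst[hi] += src[kh]; }
            else dst[clampi(hi, 0, H - 1)] += src[kh];
          }
        }
      }
    }
  }
}

// ReLU forward: returns max(x, 0) preserving dim
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (long i = 0; i < (long)x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0;
  return out;
}

// ReLU backward: g * (x > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector x) {
  NumericVector out(g.size());
  out.attr("dim") = g.attr("dim");
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* op = out.begin();
  for (long i = 0; i < (long)g.size(); ++i) op[i] = xp[i] > 0 ? gp[i] : 0;
  return out;
}

// Batch-norm forward over (H, W, N) per channel.
// mode: training (use batch stats) if `training`; otherwise uses rm/rv.
// Returns y, xhat, invstd, mean, var_biased (the R side updates running stats).
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rm, NumericVector rv, double eps, bool training) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const long plane = (long)H * W;
  const long m = plane * N;
  NumericVector y(x.size());
  y.attr("dim") = d;
  NumericVector xhat(x.size());
  xhat.attr("dim") = d;
  NumericVector mean(C), varb(C), invstd(C);
  const double* xp = x.begin();
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = xp + plane * (c + (long)C * n);
        for (long i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double mu = s / m;
      double v = s2 / m - mu * mu;
      if (v < 0) v = 0;
      mean[c] = mu; varb[c] = v; invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mean[c] = rm[c]; varb[c] = rv[c];
      invstd[c] = 1.0 / std::sqrt(rv[c] + eps);
    }
  }
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double mu = mean[c], is = invstd[c], ga = gamma[c], be = beta[c];
      const double* p = xp + plane * (c + (long)C * n);
      double* yo = yp + plane * (c + (long)C * n);
      double* ho = hp + plane * (c + (long)C * n);
      for (long i = 0; i < plane; ++i) {
        const double xh = (p[i] - mu) * is;
        ho[i] = xh;
        yo[i] = ga * xh + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = mean, _["var"] = varb);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector xhat, NumericVector invstd,
                NumericVector gamma, bool training) {
  IntegerVector d = dims4(g, "g");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const long plane = (long)H * W;
  const long m = plane * N;
  NumericVector gx(g.size());
  gx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  const double* gp = g.begin();
  const double* hp = xhat.begin();
  double* xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* gs = gp + plane * (c + (long)C * n);
      const double* hs = hp + plane * (c + (long)C * n);
      for (long i = 0; i < plane; ++i) { s1 += gs[i]; s2 += gs[i] * hs[i]; }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double ga = gamma[c], is = invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* gs = gp + plane * (c + (long)C * n);
      const double* hs = hp + plane * (c + (long)C * n);
      double* xs = xp + plane * (c + (long)C * n);
      if (training) {
        for (long i = 0; i < plane; ++i)
          xs[i] = ga * is * (gs[i] - s1 / m - hs[i] * s2 / m);
      } else {
        for (long i = 0; i < plane; ++i) xs[i] = ga * is * gs[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups, int pad_mode) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cg = dw[2], Cout = dw[3];
  if (C != Cg * groups) stop("conv2d: input has %d channels but weights expect %d (groups=%d)",
                             C, Cg * groups, groups);
  if (Cout % groups != 0) stop("conv2d: Cout not divisible by groups");
  const int Coutg = Cout / groups;
  const int HO = (H + 2 * pad - KH) / stride + 1;
  const int WO = (W + 2 * pad - KW) / stride + 1;
  if (HO <= 0 || WO <= 0) stop("conv2d: non-positive output size");

  NumericVector out((long)HO * WO * Cout * N);
  out.attr("dim") = IntegerVector::create(HO, WO, Cout, N);

  const long CKKg = (long)KH * KW * Cg;
  const long plane = (long)HO * WO;

  if (KH == 1 && KW == 1 && stride == 1 && pad == 0) {
    // pointwise convolution: plain per-image GEMM on the channel matrix
    const int Coutg1 = Cout / groups;
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat Xv(const_cast<double*>(x.begin()) +
                             (long)n * H * W * C + (long)g * Cg * plane,
                           plane, Cg, false, true);
        const arma::mat Wg(const_cast<double*>(w.begin()) + (long)g * Coutg1 * Cg,
                           Cg, Coutg1, false, true);
        arma::mat Ov(out.begin() + (long)n * plane * Cout + (long)g * Coutg1 * plane,
                     plane, Coutg1, false, true);
        Ov = Xv * Wg;
      }
    }
    if (bias.isNotNull()) {
      NumericVector b(bias);
      double* op = out.begin();
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cout; ++c) {
          double* p = op + plane * (c + (long)Cout * n);
          for (long i = 0; i < plane; ++i) p[i] += b[c];
        }
    }
    return out;
  }
  // one im2col matrix spanning the whole batch, one GEMM per channel group
  arma::mat col(CKKg, plane * N);
  const double* xp = x.begin();
  double* op = out.begin();

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      arma::mat block(col.colptr((long)n * plane), CKKg, plane, false, true);
      im2col(xp + (long)n * H * W * C, H, W, g * Cg, Cg, KH, KW, stride, pad,
             pad_mode, HO, WO, block);
    }
    const arma::mat Wg(const_cast<double*>(w.begin()) + (long)g * Coutg * CKKg,
                       CKKg, Coutg, false, true);
    arma::mat res = col.t() * Wg;  // (plane*N) x Coutg
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Coutg; ++co)
        std::memcpy(op + plane * ((long)g * Coutg + co + (long)Cout * n),
                    res.colptr(co) + (long)n * plane, plane * sizeof(double));
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    if ((int)b.size() != Cout) stop("conv2d: bias length mismatch");
    const long plane = (long)HO * WO;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double* p = op + plane * (c + (long)Cout * n);
        const double bv = b[c];
        for (long i = 0; i < plane; ++i) p[i] += bv;
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad, int groups, int pad_mode,
                    bool need_x, bool need_bias) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w"), dg = dims4(gout, "gout");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cg = dw[2], Cout = dw[3];
  const int HO = dg[0], WO = dg[1];
  if (dg[2] != Cout || dg[3] != N) stop("conv2d backward: gout shape mismatch");
  const int Coutg = Cout / groups;
  const long CKKg = (long)KH * KW * Cg;

  NumericVector gw((long)KH * KW * Cg * Cout);
  gw.attr("dim") = dw;
  NumericVector gx;
  if (need_x) {
    gx = NumericVector((long)H * W * C * N);
    gx.attr("dim") = dx;
  }
  NumericVector gb(need_bias ? Cout : 0);

  const long plane = (long)HO * WO;

  if (KH == 1 && KW == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        const arma::mat Xv(const_cast<double*>(x.begin()) +
                             (long)n * H * W * C + (long)g * Cg * plane,
                           plane, Cg, false, true);
        const arma::mat Gv(const_cast<double*>(gout.begin()) +
                             (long)n * plane * Cout + (long)g * Coutg * plane,
                           plane, Coutg, false, true);
        arma::mat GWv(gw.begin() + (long)g * Coutg * Cg, Cg, Coutg, false, true);
        GWv += Xv.t() * Gv;
        if (need_x) {
          const arma::mat Wg(const_cast<double*>(w.begin()) + (long)g * Coutg * Cg,
                             Cg, Coutg, false, true);
          arma::mat GXv(gx.begin() + (long)n * H * W * C + (long)g * Cg * plane,
                        plane, Cg, false, true);
          GXv = Gv * Wg.t();
        }
      }
    }
    if (need_bias) {
      const double* gp = gout.begin();
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cout; ++c) {
          const double* p = gp + plane * (c + (long)Cout * n);
          double s = 0.0;
          for (long i = 0; i < plane; ++i) s += p[i];
          gb[c] += s;
        }
    }
    return List::create(_["gx"] = need_x ? (SEXP)gx : R_NilValue,
                        _["gw"] = gw,
                        _["gb"] = need_bias ? (SEXP)gb : R_NilValue);
  }

  arma::mat col(CKKg, plane * N);
  arma::mat gbig(plane * N, Coutg);
  const double* xp = x.begin();
  const double* gp = gout.begin();

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      arma::mat block(col.colptr((long)n * plane), CKKg, plane, false, true);
      im2col(xp + (long)n * H * W * C, H, W, g * Cg, Cg, KH, KW, stride, pad,
             pad_mode, HO, WO, block);
      for (int co = 0; co < Coutg; ++co)
        std::memcpy(gbig.colptr(co) + (long)n * plane,
                    gp + plane * ((long)g * Coutg + co + (long)Cout * n),
                    plane * sizeof(double));
    }
    arma::mat GWv(gw.begin() + (long)g * Coutg * CKKg, CKKg, Coutg, false, true);
    GWv = col * gbig;
    if (need_x) {
      const arma::mat Wg(const_cast<double*>(w.begin()) + (long)g * Coutg * CKKg,
                         CKKg, Coutg, false, true);
      col = Wg * gbig.t();  // reuse as the gradient columns
      for (int n = 0; n < N; ++n) {
        const arma::mat block(col.colptr((long)n * plane), CKKg, plane, false, true);
        col2im(block, gx.begin() + (long)n * H * W * C, H, W, g * Cg, Cg,
               KH, KW, stride, pad, pad_mode, HO, WO);
      }
    }
  }
  if (need_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        const double* p = gp + plane * (c + (long)Cout * n);
        double s = 0.0;
        for (long i = 0; i < plane; ++i) s += p[i];
        gb[c] += s;
      }
  }
  return List::create(_["gx"] = need_x ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw,
                      _["gb"] = need_bias ? (SEXP)gb : R_NilValue);
}

// 3x3 stride-2 pad-1 max pooling (ResNet stem). Returns values and 1-based
// argmax indices into the (H*W) plane of each (c, n) slice.
// [[Rcpp::export]]
List cpp_maxpool3x3s2_fwd(NumericVector x) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int HO = (H - 1) / 2 + 1, WO = (W - 1) / 2 + 1;
  NumericVector out((long)HO * WO * C * N);
  out.attr("dim") = IntegerVector::create(HO, WO, C, N);
  IntegerVector idx((long)HO * WO * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  const long planeIn = (long)H * W, planeOut = (long)HO * WO;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xs = xp + cn * planeIn;
    double* os = op + cn * planeOut;
    int* is = ip + cn * planeOut;
    for (int wo = 0; wo < WO; ++wo) {
      for (int ho = 0; ho < HO; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        long bi = -1;
        for (int kw = 0; kw < 3; ++kw) {
          const int wi = 2 * wo - 1 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            const int hi = 2 * ho - 1 + kh;
            if (hi < 0 || hi >= H) continue;
            const double v = xs[hi + (long)H * wi];
            if (v > best) { best = v; bi = hi + (long)H * wi; }
          }
        }
        os[ho + (long)HO * wo] = best;
        is[ho + (long)HO * wo] = (int)(bi + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3x3s2_bwd(NumericVector gout, IntegerVector idx,
                                   int H, int W) {
  IntegerVector d = dims4(gout, "gout");
  const int HO = d[0], WO = d[1], C = d[2], N = d[3];
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const long planeIn = (long)H * W, planeOut = (long)HO * WO;
  const double* gp = gout.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gs = gp + cn * planeOut;
    const int* is = ip + cn * planeOut;
    double* xs = xp + cn * planeIn;
    for (long i = 0; i < planeOut; ++i) xs[is[i] - 1] += gs[i];
  }
  return gx;
}

// Bilinear resize with the half-pixel (align_corners = FALSE) convention.
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int HO, int WO) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out((long)HO * WO * C * N);
  out.attr("dim") = IntegerVector::create(HO, WO, C, N);
  const double sh = (double)H / HO, sw = (double)W / WO;
  std::vector<int> h0(HO), h1(HO), w0(WO), w1(WO);
  std::vector<double> lh(HO), lw(WO);
  for (int i = 0; i < HO; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    lh[i] = s - h0[i];
  }
  for (int j = 0; j < WO; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    lw[j] = s - w0[j];
  }
  const long planeIn = (long)H * W, planeOut = (long)HO * WO;
  const double* xp = x.begin();
  double* op = out.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xs = xp + cn * planeIn;
    double* os = op + cn * planeOut;
    for (int j = 0; j < WO; ++j) {
      const long cw0 = (long)H * w0[j], cw1 = (long)H * w1[j];
      for (int i = 0; i < HO; ++i) {
        const double a = xs[h0[i] + cw0], b = xs[h1[i] + cw0];
        const double c = xs[h0[i] + cw1], e = xs[h1[i] + cw1];
        const double top = a + lh[i] * (b - a), bot = c + lh[i] * (e - c);
        os[i + (long)HO * j] = top + lw[j] * (bot - top);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gout, int H, int W) {
  IntegerVector d = dims4(gout, "gout");
  const int HO = d[0], WO = d[1], C = d[2], N = d[3];
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / HO, sw = (double)W / WO;
  std::vector<int> h0(HO), h1(HO), w0(WO), w1(WO);
  std::vector<double> lh(HO), lw(WO);
  for (int i = 0; i < HO; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    lh[i] = s - h0[i];
  }
  for (int j = 0; j < WO; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    lw[j] = s - w0[j];
  }
  const long planeIn = (long)H * W, planeOut = (long)HO * WO;
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gs = gp + cn * planeOut;
    double* xs = xp + cn * planeIn;
    for (int j = 0; j < WO; ++j) {
      const long cw0 = (long)H * w0[j], cw1 = (long)H * w1[j];
      for (int i = 0; i < HO; ++i) {
        const double g = gs[i + (long)HO * j];
        xs[h0[i] + cw0] += g * (1 - lh[i]) * (1 - lw[j]);
        xs[h1[i] + cw0] += g * lh[i] * (1 - lw[j]);
        xs[h0[i] + cw1] += g * (1 - lh[i]) * lw[j];
        xs[h1[i] + cw1] += g * lh[i] * lw[j];
      }
    }
  }
  return gx;
}

// In-place Adam update (decoupled nothing: classic L2-in-gradient weight decay,
// as in the reference framework's Adam). p, m, v are modified in place; they
// are private buffers owned by the optimizer/parameter environments.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double beta1, double beta2,
                   double eps, double weight_decay, int t) {
  const long n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam: buffer length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (long i = 0; i < n; ++i) {
    const double gi = gp[i] + weight_decay * pp[i];
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gi;
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gi * gi;
    const double mhat = mp[i] / bc1, vhat = vp[i] / bc2;
    pp[i] -= lr * mhat / (std::sqrt(vhat) + eps);
  }
}
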