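// Compiled numeric kernels for the network layers.
//
// Array conventions (R column-major):
//   2-D feature map: dim (H, W, C)
//   3-D (video) feature: dim (T, H, W, C)
//   conv2d weight (kh, kw, Cin, Cout); depthwise weight (kh, kw, C);
//   conv3d weight (kt, kh, kw, Cin, Cout).
// All convolutions are same-padded, stride 1, odd kernel sizes.
// Pooling is non-overlapping (stride = pool) except maxpool3d_s1 (stride 1,
// same-padded), used by the inception pooling branch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("input must be a dim-ed array");
  return IntegerVector(d);
}

// ---------------------------------------------------------------- conv2d ----

// im2col for (H,W,C) input, kernel (kh,kw), same padding.
static arma::mat im2col2d(const NumericVector& x, int H, int W, int C,
                          int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::mat cols(H * (long)W, (long)kh * kw * C, arma::fill::zeros);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const long r = dh + (long)kh * dw + (long)kh * kw * c;
        for (int j = 0; j < W; ++j) {
          const int js = j + dw - pw;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dh - ph;
            if (is < 0 || is >= H) continue;
            cols(i + (long)H * j, r) = xp[is + (long)H * js + (long)H * W * c];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  arma::mat cols = im2col2d(x, H, W, C, kh, kw);
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false);
  arma::mat Y = cols * Wm;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  arma::mat cols = im2col2d(x, H, W, C, kh, kw);
  arma::mat GY(const_cast<double*>(gy.begin()), (long)H * W, Cout, false);
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false);
  arma::mat GW = cols.t() * GY;
  arma::rowvec GB = arma::sum(GY, 0);
  arma::mat GC = GY * Wm.t();  // (H*W) x (kh*kw*Cin)
  NumericVector gx(x.size());
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const long r = dh + (long)kh * dw + (long)kh * kw * c;
        for (int j = 0; j < W; ++j) {
          const int js = j + dw - pw;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dh - ph;
            if (is < 0 || is >= H) continue;
            gxp[is + (long)H * js + (long)H * W * c] += GC(i + (long)H * j, r);
          }
        }
      }
  gx.attr("dim") = xd;
  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// ------------------------------------------------------- depthwise conv2d ----

// [[Rcpp::export(name = ".cpp_dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("depthwise conv: one kernel per input channel required");
  const int ph = kh / 2, pw = kw / 2;
  NumericVector y(x.size());
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)H * W * c;
    const double* wc = wp + (long)kh * kw * c;
    double* yc = yp + (long)H * W * c;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double acc = b[c];
        for (int dw = 0; dw < kw; ++dw) {
          const int js = j + dw - pw;
          if (js < 0 || js >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int is = i + dh - ph;
            if (is < 0 || is >= H) continue;
            acc += wc[dh + kh * dw] * xc[is + (long)H * js];
          }
        }
        yc[i + (long)H * j] = acc;
      }
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector gx(x.size()), gw(w.size()), gb(C);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* gp = gy.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)H * W * c;
    const double* wc = wp + (long)kh * kw * c;
    const double* gc = gp + (long)H * W * c;
    double* gxc = gx.begin() + (long)H * W * c;
    double* gwc = gw.begin() + (long)kh * kw * c;
    double accb = 0.0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double g = gc[i + (long)H * j];
        accb += g;
        for (int dw = 0; dw < kw; ++dw) {
          const int js = j + dw - pw;
          if (js < 0 || js >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int is = i + dh - ph;
            if (is < 0 || is >= H) continue;
            gwc[dh + kh * dw] += g * xc[is + (long)H * js];
            gxc[is + (long)H * js] += g * wc[dh + kh * dw];
          }
        }
      }
    gb[c] = accb;
  }
  gx.attr("dim") = xd; gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------- conv3d ----

static arma::mat im2col3d(const NumericVector& x, int T, int H, int W, int C,
                          int kt, int kh, int kw) {
  const int pt = kt / 2, ph = kh / 2, pw = kw / 2;
  const long P = (long)T * H * W;
  arma::mat cols(P, (long)kt * kh * kw * C, arma::fill::zeros);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh)
        for (int dt = 0; dt < kt; ++dt) {
          const long r = dt + (long)kt * dh + (long)kt * kh * dw +
                         (long)kt * kh * kw * c;
          for (int j = 0; j < W; ++j) {
            const int js = j + dw - pw;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + dh - ph;
              if (is < 0 || is >= H) continue;
              for (int t = 0; t < T; ++t) {
                const int ts = t + dt - pt;
                if (ts < 0 || ts >= T) continue;
                cols(t + (long)T * i + (long)T * H * j, r) =
                  xp[ts + (long)T * is + (long)T * H * js + (long)T * H * W * c];
              }
            }
          }
        }
  return cols;
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: channel mismatch");
  arma::mat cols = im2col3d(x, T, H, W, C, kt, kh, kw);
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kt * kh * kw * Cin, Cout, false);
  arma::mat Y = cols * Wm;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(T, H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kt = wd[0], kh = wd[1], kw = wd[2], Cin = wd[3], Cout = wd[4];
  const int pt = kt / 2, ph = kh / 2, pw = kw / 2;
  const long P = (long)T * H * W;
  arma::mat cols = im2col3d(x, T, H, W, C, kt, kh, kw);
  arma::mat GY(const_cast<double*>(gy.begin()), P, Cout, false);
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kt * kh * kw * Cin, Cout, false);
  arma::mat GW = cols.t() * GY;
  arma::rowvec GB = arma::sum(GY, 0);
  arma::mat GC = GY * Wm.t();
  NumericVector gx(x.size());
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh)
        for (int dt = 0; dt < kt; ++dt) {
          const long r = dt + (long)kt * dh + (long)kt * kh * dw +
                         (long)kt * kh * kw * c;
          for (int j = 0; j < W; ++j) {
            const int js = j + dw - pw;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + dh - ph;
              if (is < 0 || is >= H) continue;
              for (int t = 0; t < T; ++t) {
                const int ts = t + dt - pt;
                if (ts < 0 || ts >= T) continue;
                gxp[ts + (long)T * is + (long)T * H * js + (long)T * H * W * c] +=
                  GC(t + (long)T * i + (long)T * H * j, r);
              }
            }
          }
        }
  gx.attr("dim") = xd;
  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// --------------------------------------------------------------- pooling ----

// [[Rcpp::export(name = ".cpp_maxpool2d_fwd")]]
List maxpool2d_fwd(NumericVector x, int ph, int pw) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y((long)Ho * Wo * C);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        double best = -INFINITY; long bi = -1;
        for (int dj = 0; dj < pw; ++dj)
          for (int di = 0; di < ph; ++di) {
            const long li = (io * ph + di) + (long)H * (jo * pw + dj) +
                            (long)H * W * c;
            if (xp[li] > best) { best = xp[li]; bi = li; }
          }
        const long lo = io + (long)Ho * jo + (long)Ho * Wo * c;
        y[lo] = best; idx[lo] = (int)bi;
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, int pt, int ph, int pw) {
  IntegerVector xd = dims_of(x);
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int To = T / pt, Ho = H / ph, Wo = W / pw;
  NumericVector y((long)To * Ho * Wo * C);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        for (int to = 0; to < To; ++to) {
          double best = -INFINITY; long bi = -1;
          for (int dj = 0; dj < pw; ++dj)
            for (int di = 0; di < ph; ++di)
              for (int dt = 0; dt < pt; ++dt) {
                const long li = (to * pt + dt) + (long)T * (io * ph + di) +
                                (long)T * H * (jo * pw + dj) + (long)T * H * W * c;
                if (xp[li] > best) { best = xp[li]; bi = li; }
              }
          const long lo = to + (long)To * io + (long)To * Ho * jo +
                          (long)To * Ho * Wo * c;
          y[lo] = best; idx[lo] = (int)bi;
        }
  y.attr("dim") = IntegerVector::create(To, Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// stride-1 same-padded 3-D max pool (window clipped at borders).
// [[Rcpp::export(name = ".cpp_maxpool3d_s1_fwd")]]
List maxpool3d_s1_fwd(NumericVector x, int kt, int kh, int kw) {
  IntegerVector xd = dims_of(x);
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int pt = kt / 2, ph = kh / 2, pw = kw / 2;
  NumericVector y(x.size());
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        for (int t = 0; t < T; ++t) {
          double best = -INFINITY; long bi = -1;
          for (int dj = -pw; dj <= pw; ++dj) {
            const int js = j + dj; if (js < 0 || js >= W) continue;
            for (int di = -ph; di <= ph; ++di) {
              const int is = i + di; if (is < 0 || is >= H) continue;
              for (int dt = -pt; dt <= pt; ++dt) {
                const int ts = t + dt; if (ts < 0 || ts >= T) continue;
                const long li = ts + (long)T * is + (long)T * H * js +
                                (long)T * H * W * c;
                if (xp[li] > best) { best = xp[li]; bi = li; }
              }
            }
          }
          const long lo = t + (long)T * i + (long)T * H * j + (long)T * H * W * c;
          y[lo] = best; idx[lo] = (int)bi;
        }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// scatter-add pooled gradients back through stored argmax indices
// [[Rcpp::export(name = ".cpp_pool_bwd")]]
NumericVector pool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  long n = 1; for (int k = 0; k < xdim.size(); ++k) n *= xdim[k];
  NumericVector gx(n);
  for (long i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export(name = ".cpp_avgpool3d_fwd")]]
NumericVector avgpool3d_fwd(NumericVector x, int pt, int ph, int pw) {
  IntegerVector xd = dims_of(x);
  const int T = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int To = T / pt, Ho = H / ph, Wo = W / pw;
  const double inv = 1.0 / ((double)pt * ph * pw);
  NumericVector y((long)To * Ho * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        for (int to = 0; to < To; ++to) {
          double acc = 0.0;
          for (int dj = 0; dj < pw; ++dj)
            for (int di = 0; di < ph; ++di)
              for (int dt = 0; dt < pt; ++dt)
                acc += xp[(to * pt + dt) + (long)T * (io * ph + di) +
                          (long)T * H * (jo * pw + dj) + (long)T * H * W * c];
          y[to + (long)To * io + (long)To * Ho * jo + (long)To * Ho * Wo * c] =
            acc * inv;
        }
  y.attr("dim") = IntegerVector::create(To, Ho, Wo, C);
  return y;
}

// [[Rcpp::export(name = ".cpp_avgpool3d_bwd")]]
NumericVector avgpool3d_bwd(NumericVector gy, IntegerVector xdim,
                            int pt, int ph, int pw) {
  const int T = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int To = T / pt, Ho = H / ph, Wo = W / pw;
  const double inv = 1.0 / ((double)pt * ph * pw);
  NumericVector gx((long)T * H * W * C);
  const double* gp = gy.begin();
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        for (int to = 0; to < To; ++to) {
          const double g = gp[to + (long)To * io + (long)To * Ho * jo +
                              (long)To * Ho * Wo * c] * inv;
          for (int dj = 0; dj < pw; ++dj)
            for (int di = 0; di < ph; ++di)
              for (int dt = 0; dt < pt; ++dt)
                gx[(to * pt + dt) + (long)T * (io * ph + di) +
                   (long)T * H * (jo * pw + dj) + (long)T * H * W * c] += g;
        }
  gx.attr("dim") = xdim;
  return gx;
}

// -------------------------------------------------------------- resizing ----

// bilinear resize of a single-channel image (half-pixel centers)
// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix img, int oh, int ow) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fc = (j + 0.5) * sc - 0.5;
    if (fc < 0) fc = 0; if (fc > W - 1) fc = W - 1;
    const int c0 = (int)fc, c1 = c0 + 1 < W ? c0 + 1 : c0;
    const double wc = fc - c0;
    for (int i = 0; i < oh; ++i) {
      double fr = (i + 0.5) * sr - 0.5;
      if (fr < 0) fr = 0; if (fr > H - 1) fr = H - 1;
      const int r0 = (int)fr, r1 = r0 + 1 < H ? r0 + 1 : r0;
      const double wr = fr - r0;
      out(i, j) = (1 - wr) * ((1 - wc) * img(r0, c0) + wc * img(r0, c1)) +
                  wr * ((1 - wc) * img(r1, c0) + wc * img(r1, c1));
    }
  }
  return out;
}
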