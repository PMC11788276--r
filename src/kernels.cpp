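// Low-level dense kernels for the network layers.
//
// Feature maps are R arrays with dim c(H, W, C, N) (column-major, H fastest).
// Convolution weights are arrays with dim c(kh, kw, C_in, C_out); the patch
// matrix uses tap order (ikh, ikw, c) with ikh fastest, so that
// matrix(W, kh*kw*C_in, C_out) lines up with it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (size_t)h + (size_t)H * ((size_t)w + (size_t)W * ((size_t)c + (size_t)C * (size_t)n));
}

// Fused convolution: per-sample im2col into a reusable buffer + GEMM +
// direct permute into the (Ho, Wo, C_out, N) output array. The patch matrix
// never crosses into R; the backward pass regathers it from the cached input.

static void gather_sample(arma::mat& K, const double* xp, int H, int W, int C,
                          int kh, int kw, int sh, int sw, int ph, int pw,
                          int Ho, int Wo) {
  K.zeros();
  for (int c = 0; c < C; ++c)
    for (int ikw = 0; ikw < kw; ++ikw)
      for (int ikh = 0; ikh < kh; ++ikh) {
        double* colp = K.colptr((size_t)ikh + kh * ((size_t)ikw + kw * c));
        int ho_lo = std::max(0, (ph - ikh + sh - 1) / sh);
        int ho_hi = Ho - 1;
        while (ho_hi >= 0 && ho_hi * sh - ph + ikh >= H) --ho_hi;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + ikw;
          if (wi < 0 || wi >= W) continue;
          double* dst = colp + (size_t)Ho * wo;
          const double* srcbase = xp + (size_t)H * (wi + (size_t)W * c);
          if (sh == 1)
            std::memcpy(dst + ho_lo, srcbase + (ho_lo - ph + ikh),
                        (size_t)(ho_hi - ho_lo + 1) * sizeof(double));
          else
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho] = srcbase[ho * sh - ph + ikh];
        }
      }
}

static void scatter_sample(const arma::mat& dK, double* xp, int H, int W, int C,
                           int kh, int kw, int sh, int sw, int ph, int pw,
                           int Ho, int Wo) {
  for (int c = 0; c < C; ++c)
    for (int ikw = 0; ikw < kw; ++ikw)
      for (int ikh = 0; ikh < kh; ++ikh) {
        const double* colp = dK.colptr((size_t)ikh + kh * ((size_t)ikw + kw * c));
        int ho_lo = std::max(0, (ph - ikh + sh - 1) / sh);
        int ho_hi = Ho - 1;
        while (ho_hi >= 0 && ho_hi * sh - ph + ikh >= H) --ho_hi;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + ikw;
          if (wi < 0 || wi >= W) continue;
          const double* src = colp + (size_t)Ho * wo;
          double* dstbase = xp + (size_t)H * (wi + (size_t)W * c);
          for (int ho = ho_lo; ho <= ho_hi; ++ho)
            dstbase[ho * sh - ph + ikh] += src[ho];
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(const NumericVector& x, int H, int W, int C, int N,
                            const arma::mat& Wm, Nullable<NumericVector> bias,
                            int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int Cout = Wm.n_cols;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  double* op = out.begin();
  const double* xp = x.begin();
  arma::mat K((size_t)Ho * Wo, (size_t)kh * kw * C);
  const bool has_bias = bias.isNotNull();
  NumericVector b = has_bias ? NumericVector(bias) : NumericVector(0);
  const size_t blk = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    gather_sample(K, xp + (size_t)H * W * C * n, H, W, C,
                  kh, kw, sh, sw, ph, pw, Ho, Wo);
    arma::mat Y = K * Wm;                     // (Ho*Wo) x Cout
    for (int co = 0; co < Cout; ++co) {
      double* dst = op + blk * (co + (size_t)Cout * n);
      const double* src = Y.colptr(co);
      if (has_bias) {
        const double bv = b[co];
        for (size_t i = 0; i < blk; ++i) dst[i] = src[i] + bv;
      } else {
        std::memcpy(dst, src, blk * sizeof(double));
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const NumericVector& x, const arma::mat& Wm,
                   const NumericVector& gy, int H, int W, int C, int N,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   bool need_bias) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int Cout = Wm.n_cols;
  const size_t blk = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dW((size_t)kh * kw * C, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  arma::mat K(blk, (size_t)kh * kw * C);
  arma::mat G(blk, Cout);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = gp + blk * (co + (size_t)Cout * n);
      std::memcpy(G.colptr(co), src, blk * sizeof(double));
      if (need_bias) {
        double s = 0;
        for (size_t i = 0; i < blk; ++i) s += src[i];
        db[co] += s;
      }
    }
    gather_sample(K, xp + (size_t)H * W * C * n, H, W, C,
                  kh, kw, sh, sw, ph, pw, Ho, Wo);
    dW += K.t() * G;
    arma::mat dK = G * Wm.t();
    scatter_sample(dK, dxp + (size_t)H * W * C * n, H, W, C,
                   kh, kw, sh, sw, ph, pw, Ho, Wo);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  if (need_bias)
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// Fused batch-norm + SiLU forward (one pass each for stats and transform).
// scale = gamma / sqrt(var + eps), shift = beta - mean * scale;
// z = x*scale + shift; y = z * sigmoid(z). Returns y and z.
// [[Rcpp::export]]
List cpp_bn_silu_fw(const NumericVector& x, int HW, int C, int N,
                    const NumericVector& scale, const NumericVector& shift) {
  NumericVector y(x.size()), z(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  double* zp = z.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = scale[c], sh = shift[c];
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) {
        const double zv = xp[off + i] * sc + sh;
        zp[off + i] = zv;
        yp[off + i] = zv / (1.0 + std::exp(-zv));
      }
    }
  return List::create(_["y"] = y, _["z"] = z);
}

// Backward of the fused SiLU part: given z and gy, returns gz.
// [[Rcpp::export]]
NumericVector cpp_silu_bw(const NumericVector& z, const NumericVector& gy) {
  NumericVector gz(z.size());
  const double* zp = z.begin();
  const double* gp = gy.begin();
  double* op = gz.begin();
  const R_xlen_t M = z.size();
  for (R_xlen_t i = 0; i < M; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-zp[i]));
    op[i] = gp[i] * s * (1.0 + zp[i] * (1.0 - s));
  }
  return gz;
}

// per-channel sums over (HW, N) for a (HW, C, N) array
// [[Rcpp::export]]
NumericVector cpp_channel_sums(const NumericVector& x, int HW, int C, int N) {
  NumericVector out(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) s += xp[off + i];
      out[c] += s;
    }
  return out;
}

// per-channel sums of x and x^2 (for batch statistics) in one pass
// [[Rcpp::export]]
List cpp_channel_stats(const NumericVector& x, int HW, int C, int N) {
  NumericVector s1(C), s2(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double a = 0, b = 0;
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) {
        const double v = xp[off + i];
        a += v; b += v * v;
      }
      s1[c] += a; s2[c] += b;
    }
  return List::create(_["sum"] = s1, _["sumsq"] = s2);
}

// Max pooling, kernel k, stride s; padding acts as -inf (padded cells never
// win). Returns values and 0-based argmax linear indices into the input
// array, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& x, int H, int W, int C, int N,
                 int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  NumericVector arg((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int ikw = 0; ikw < k; ++ikw) {
            const int wi = wo * s - p + ikw;
            if (wi < 0 || wi >= W) continue;
            for (int ikh = 0; ikh < k; ++ikh) {
              const int hi = ho * s - p + ikh;
              if (hi < 0 || hi >= H) continue;
              const size_t ii = idx4(hi, wi, c, n, H, W, C);
              if (xp[ii] > best) { best = xp[ii]; besti = ii; }
            }
          }
          const size_t oo = (size_t)ho + (size_t)Ho * ((size_t)wo + (size_t)Wo * ((size_t)c + (size_t)C * n));
          yp[oo] = best;
          ap[oo] = (double)besti;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& gy, const NumericVector& argmax,
                                   int H, int W, int C, int N) {
  NumericVector gx((size_t)H * W * C * N);
  double* gp = gx.begin();
  const double* gyp = gy.begin();
  const double* ap = argmax.begin();
  const R_xlen_t M = gy.size();
  for (R_xlen_t i = 0; i < M; ++i) gp[(size_t)ap[i]] += gyp[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// Bilinear gather: sample x (H,W,C,N) at M floating-point locations per image.
// ys, xs are M x N matrices of 0-based pixel coordinates (row, col), assumed
// already clamped to [0, H-1] / [0, W-1]. Output dim (M, C, N): sample index
// fastest, shared across channels.
// [[Rcpp::export]]
NumericVector cpp_bilinear_gather(const NumericVector& x, int H, int W, int C, int N,
                                  const arma::mat& ys, const arma::mat& xs) {
  const int M = ys.n_rows;
  NumericVector out((size_t)M * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int m = 0; m < M; ++m) {
      const double yy = ys(m, n), xx = xs(m, n);
      const int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
      const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
      const int y0c = std::max(0, std::min(y0, H - 1));
      const int x0c = std::max(0, std::min(x0, W - 1));
      const double fy = yy - y0, fx = xx - x0;
      const double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx;
      const double w10 = fy * (1 - fx), w11 = fy * fx;
      for (int c = 0; c < C; ++c) {
        const double v =
          w00 * xp[idx4(y0c, x0c, c, n, H, W, C)] +
          w01 * xp[idx4(y0c, x1, c, n, H, W, C)] +
          w10 * xp[idx4(y1, x0c, c, n, H, W, C)] +
          w11 * xp[idx4(y1, x1, c, n, H, W, C)];
        op[(size_t)m + (size_t)M * ((size_t)c + (size_t)C * n)] = v;
      }
    }
  out.attr("dim") = IntegerVector::create(M, C, N);
  return out;
}

// Backward of cpp_bilinear_gather: gradients w.r.t. x and the coordinates.
// [[Rcpp::export]]
List cpp_bilinear_gather_backward(const NumericVector& x, int H, int W, int C, int N,
                                  const arma::mat& ys, const arma::mat& xs,
                                  const NumericVector& gout) {
  const int M = ys.n_rows;
  NumericVector gx((size_t)H * W * C * N);
  arma::mat gys(M, N, arma::fill::zeros), gxs(M, N, arma::fill::zeros);
  const double* xp = x.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int m = 0; m < M; ++m) {
      const double yy = ys(m, n), xx = xs(m, n);
      const int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
      const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
      const int y0c = std::max(0, std::min(y0, H - 1));
      const int x0c = std::max(0, std::min(x0, W - 1));
      const double fy = yy - y0, fx = xx - x0;
      const double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx;
      const double w10 = fy * (1 - fx), w11 = fy * fx;
      double gy_acc = 0, gx_acc = 0;
      for (int c = 0; c < C; ++c) {
        const double g = gp[(size_t)m + (size_t)M * ((size_t)c + (size_t)C * n)];
        const size_t i00 = idx4(y0c, x0c, c, n, H, W, C);
        const size_t i01 = idx4(y0c, x1, c, n, H, W, C);
        const size_t i10 = idx4(y1, x0c, c, n, H, W, C);
        const size_t i11 = idx4(y1, x1, c, n, H, W, C);
        gxp[i00] += g * w00; gxp[i01] += g * w01;
        gxp[i10] += g * w10; gxp[i11] += g * w11;
        const double v00 = xp[i00], v01 = xp[i01], v10 = xp[i10], v11 = xp[i11];
        gy_acc += g * (-(1 - fx) * v00 - fx * v01 + (1 - fx) * v10 + fx * v11);
        gx_acc += g * (-(1 - fy) * v00 + (1 - fy) * v01 - fy * v10 + fy * v11);
      }
      gys(m, n) = gy_acc;
      gxs(m, n) = gx_acc;
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["gx"] = gx, _["gys"] = gys, _["gxs"] = gxs);
}
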