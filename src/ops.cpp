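#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Tensors are column-major R arrays with dim (H, W, C, N).
// im2col column order: channel-major, then kernel column, kernel row fastest,
// matching the row layout of the conv weight matrix (kh*kw*C x F).

static inline R_xlen_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pt, int pl,
                         int OH, int OW) {
  NumericMatrix out((double)OH * OW * N, kh * kw * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)OH * OW * N;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        R_xlen_t col = (R_xlen_t)c * kh * kw + (R_xlen_t)j * kh + i;
        double *dst = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int ow = 0; ow < OW; ++ow) {
            int wsrc = ow * stride - pl + j;
            R_xlen_t base = (R_xlen_t)n * OH * OW + (R_xlen_t)ow * OH;
            if (wsrc < 0 || wsrc >= W) {
              std::memset(dst + base, 0, sizeof(double) * OH);
              continue;
            }
            if (stride == 1) {
              // contiguous strip: oh such that oh - pt + i lies in [0, H)
              int lo = std::max(0, pt - i);
              int hi = std::min(OH, H + pt - i);  // exclusive
              if (lo > 0) std::memset(dst + base, 0, sizeof(double) * lo);
              if (hi < OH)
                std::memset(dst + base + hi, 0, sizeof(double) * (OH - hi));
              if (hi > lo)
                std::memcpy(dst + base + lo,
                            px + idx4(lo - pt + i, wsrc, c, n, H, W, C),
                            sizeof(double) * (hi - lo));
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                int hsrc = oh * stride - pt + i;
                dst[base + oh] = (hsrc < 0 || hsrc >= H)
                  ? 0.0 : px[idx4(hsrc, wsrc, c, n, H, W, C)];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pt, int pl,
                         int OH, int OW) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *pdx = dx.begin();
  const double *pc = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)OH * OW * N;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        R_xlen_t col = (R_xlen_t)c * kh * kw + (R_xlen_t)j * kh + i;
        const double *src = pc + col * nrow;
        for (int n = 0; n < N; ++n) {
          for (int ow = 0; ow < OW; ++ow) {
            int wsrc = ow * stride - pl + j;
            if (wsrc < 0 || wsrc >= W) continue;
            R_xlen_t base = (R_xlen_t)n * OH * OW + (R_xlen_t)ow * OH;
            if (stride == 1) {
              int lo = std::max(0, pt - i);
              int hi = std::min(OH, H + pt - i);
              double *d = pdx + idx4(lo - pt + i, wsrc, c, n, H, W, C);
              const double *s = src + base + lo;
              for (int k = 0; k < hi - lo; ++k) d[k] += s[k];
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                int hsrc = oh * stride - pt + i;
                if (hsrc < 0 || hsrc >= H) continue;
                pdx[idx4(hsrc, wsrc, c, n, H, W, C)] += src[base + oh];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Depthwise convolution: one kh x kw kernel per input channel.
// wmat is (kh*kw) x C (kernel row fastest), bias length C.

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                             NumericMatrix wmat, NumericVector bias,
                             int kh, int kw, int stride, int pt, int pl,
                             int OH, int OW) {
  NumericVector y((R_xlen_t)OH * OW * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *wk = &wmat(0, c);
      const double *xp = px + idx4(0, 0, c, n, H, W, C);
      double *yp = py + idx4(0, 0, c, n, OH, OW, C);
      double b = bias.size() ? bias[c] : 0.0;
      for (R_xlen_t k = 0; k < (R_xlen_t)OH * OW; ++k) yp[k] = b;
      if (stride == 1) {
        // accumulate kh*kw shifted-plane AXPYs over the valid rectangle
        for (int j = 0; j < kw; ++j) {
          int wlo = std::max(0, pl - j), whi = std::min(OW, W + pl - j);
          for (int i = 0; i < kh; ++i) {
            int hlo = std::max(0, pt - i), hhi = std::min(OH, H + pt - i);
            double wv = wk[j * kh + i];
            if (wv == 0.0) continue;
            for (int ow = wlo; ow < whi; ++ow) {
              const double *s = xp + (R_xlen_t)(ow - pl + j) * H + (hlo - pt + i);
              double *d = yp + (R_xlen_t)ow * OH + hlo;
              for (int k = 0; k < hhi - hlo; ++k) d[k] += wv * s[k];
            }
          }
        }
      } else {
        for (int ow = 0; ow < OW; ++ow) {
          for (int oh = 0; oh < OH; ++oh) {
            double acc = yp[(R_xlen_t)ow * OH + oh];
            for (int j = 0; j < kw; ++j) {
              int wsrc = ow * stride - pl + j;
              if (wsrc < 0 || wsrc >= W) continue;
              for (int i = 0; i < kh; ++i) {
                int hsrc = oh * stride - pt + i;
                if (hsrc < 0 || hsrc >= H) continue;
                acc += wk[j * kh + i] * xp[(R_xlen_t)wsrc * H + hsrc];
              }
            }
            yp[(R_xlen_t)ow * OH + oh] = acc;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector dy, int H, int W, int C,
                    int N, NumericMatrix wmat, int kh, int kw, int stride,
                    int pt, int pl, int OH, int OW, bool has_bias) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericMatrix dw(kh * kw, C);
  NumericVector db(has_bias ? C : 0);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *wk = &wmat(0, c);
      double *dwk = &dw(0, c);
      const double *xp = px + idx4(0, 0, c, n, H, W, C);
      const double *gp = pdy + idx4(0, 0, c, n, OH, OW, C);
      double *dxp = pdx + idx4(0, 0, c, n, H, W, C);
      if (has_bias) {
        double s = 0.0;
        for (R_xlen_t k = 0; k < (R_xlen_t)OH * OW; ++k) s += gp[k];
        db[c] += s;
      }
      if (stride == 1) {
        for (int j = 0; j < kw; ++j) {
          int wlo = std::max(0, pl - j), whi = std::min(OW, W + pl - j);
          for (int i = 0; i < kh; ++i) {
            int hlo = std::max(0, pt - i), hhi = std::min(OH, H + pt - i);
            double wv = wk[j * kh + i];
            double acc = 0.0;
            for (int ow = wlo; ow < whi; ++ow) {
              const double *xs = xp + (R_xlen_t)(ow - pl + j) * H + (hlo - pt + i);
              double *dxs = dxp + (R_xlen_t)(ow - pl + j) * H + (hlo - pt + i);
              const double *g = gp + (R_xlen_t)ow * OH + hlo;
              int len = hhi - hlo;
              for (int k = 0; k < len; ++k) {
                acc += g[k] * xs[k];
                dxs[k] += wv * g[k];
              }
            }
            dwk[j * kh + i] += acc;
          }
        }
      } else {
        for (int ow = 0; ow < OW; ++ow) {
          for (int oh = 0; oh < OH; ++oh) {
            double g = gp[(R_xlen_t)ow * OH + oh];
            for (int j = 0; j < kw; ++j) {
              int wsrc = ow * stride - pl + j;
              if (wsrc < 0 || wsrc >= W) continue;
              for (int i = 0; i < kh; ++i) {
                int hsrc = oh * stride - pt + i;
                if (hsrc < 0 || hsrc >= H) continue;
                dwk[j * kh + i] += g * xp[(R_xlen_t)wsrc * H + hsrc];
                dxp[(R_xlen_t)wsrc * H + hsrc] += g * wk[j * kh + i];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                     int kh, int kw, int stride, int pt, int pl,
                     int OH, int OW) {
  NumericVector y((R_xlen_t)OH * OW * C * N);
  IntegerVector arg((R_xlen_t)OH * OW * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = px + idx4(0, 0, c, n, H, W, C);
      R_xlen_t off = idx4(0, 0, c, n, H, W, C);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int j = 0; j < kw; ++j) {
            int wsrc = ow * stride - pl + j;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hsrc = oh * stride - pt + i;
              if (hsrc < 0 || hsrc >= H) continue;
              R_xlen_t xi = (R_xlen_t)wsrc * H + hsrc;
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          R_xlen_t yi = idx4(oh, ow, c, n, OH, OW, C);
          py[yi] = best;
          pa[yi] = (int)(off + besti);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["out"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector argmax, NumericVector dy,
                              int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const int *pa = argmax.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k)
    if (pa[k] >= 0) pdx[pa[k]] += pdy[k];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Bilinear resize of a single (H, W, C) image with pixel-centre alignment.

// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(NumericVector x, int H, int W, int C,
                                  int OH, int OW) {
  NumericVector y((R_xlen_t)OH * OW * C);
  const double *px = x.begin();
  double *py = y.begin();
  double sh = (double)H / OH, sw = (double)W / OW;
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < OW; ++ow) {
      double ws = (ow + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(ws);
      double fw = ws - w0;
      int w0c = std::min(std::max(w0, 0), W - 1);
      int w1c = std::min(std::max(w0 + 1, 0), W - 1);
      for (int oh = 0; oh < OH; ++oh) {
        double hs = (oh + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(hs);
        double fh = hs - h0;
        int h0c = std::min(std::max(h0, 0), H - 1);
        int h1c = std::min(std::max(h0 + 1, 0), H - 1);
        double v00 = px[h0c + (R_xlen_t)H * (w0c + (R_xlen_t)W * c)];
        double v10 = px[h1c + (R_xlen_t)H * (w0c + (R_xlen_t)W * c)];
        double v01 = px[h0c + (R_xlen_t)H * (w1c + (R_xlen_t)W * c)];
        double v11 = px[h1c + (R_xlen_t)H * (w1c + (R_xlen_t)W * c)];
        py[oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * c)] =
          (1 - fh) * (1 - fw) * v00 + fh * (1 - fw) * v10 +
          (1 - fh) * fw * v01 + fh * fw * v11;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C);
  return y;
}
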