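// Low-level numerical kernels for feature maps stored as R arrays with
// dim = c(H, W, C, B) (column-major, row index fastest).  All kernels are
// single-threaded and allocation-exact so results are bit-reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t IDX(int h, int w, int c, int b, int H, int W, int C) {
  return (R_xlen_t)h + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * ((R_xlen_t)c + (R_xlen_t)C * b));
}

static inline int out_size(int in, int k, int stride, int pad0, int pad1) {
  return (in + pad0 + pad1 - k) / stride + 1;
}

// Dense 2-D convolution (cross-correlation, as in CNN practice).
// x: [H,W,Cin,B], w: [kh,kw,Cin,Cout], bias: length Cout (may be all zero).
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int padT, int padB, int padL, int padR) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = out_size(H, kh, stride, padT, padB);
  int Wo = out_size(W, kw, stride, padL, padR);
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * Cout * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  const double* px = x.begin(); const double* pw = w.begin();
  double* py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias[co];
          int h0 = ho * stride - padT, w0 = wo * stride - padL;
          for (int ci = 0; ci < Cin; ++ci)
            for (int kj = 0; kj < kw; ++kj) {
              int wi = w0 + kj; if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                int hi = h0 + ki; if (hi < 0 || hi >= H) continue;
                acc += px[IDX(hi, wi, ci, b, H, W, Cin)] *
                       pw[(R_xlen_t)ki + kh * ((R_xlen_t)kj + kw * ((R_xlen_t)ci + (R_xlen_t)Cin * co))];
              }
            }
          py[IDX(ho, wo, co, b, Ho, Wo, Cout)] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int padT, int padB, int padL, int padR) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((R_xlen_t)H * W * Cin * B), gw((R_xlen_t)kh * kw * Cin * Cout), gb(Cout);
  gx.attr("dim") = xd; gw.attr("dim") = wd;
  const double* px = x.begin(); const double* pw = w.begin(); const double* pg = gy.begin();
  double* pgx = gx.begin(); double* pgw = gw.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = pg[IDX(ho, wo, co, b, Ho, Wo, Cout)];
          if (g == 0.0) { continue; }
          gb[co] += g;
          int h0 = ho * stride - padT, w0 = wo * stride - padL;
          for (int ci = 0; ci < Cin; ++ci)
            for (int kj = 0; kj < kw; ++kj) {
              int wi = w0 + kj; if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                int hi = h0 + ki; if (hi < 0 || hi >= H) continue;
                R_xlen_t xi = IDX(hi, wi, ci, b, H, W, Cin);
                R_xlen_t wi2 = (R_xlen_t)ki + kh * ((R_xlen_t)kj + kw * ((R_xlen_t)ci + (R_xlen_t)Cin * co));
                pgx[xi] += g * pw[wi2];
                pgw[wi2] += g * px[xi];
              }
            }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// valid output range [lo, hi) for one kernel tap: need
// 0 <= o*stride - pad + k < n
static inline void tap_range(int n, int out, int stride, int pad, int k,
                             int& lo, int& hi) {
  int a = pad - k;                       // need o*stride >= a
  lo = (a <= 0) ? 0 : (a + stride - 1) / stride;
  int b = n - 1 + pad - k;               // need o*stride <= b
  hi = (b < 0) ? 0 : b / stride + 1;
  if (hi > out) hi = out;
  if (lo > hi) lo = hi;
}

// Depthwise convolution: one spatial kernel per channel, no channel mixing.
// x: [H,W,C,B], w: [kh,kw,C], bias: length C.  Loops are ordered tap-first
// with precomputed valid output ranges so the hot loops are check-free.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int padT, int padB, int padL, int padR) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = out_size(H, kh, stride, padT, padB);
  int Wo = out_size(W, kw, stride, padL, padR);
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* px = x.begin(); const double* pw = w.begin();
  double* py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* yc = py + IDX(0, 0, c, b, Ho, Wo, C);
      const double* xc = px + IDX(0, 0, c, b, H, W, C);
      double bc = bias[c];
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) yc[i] = bc;
      for (int kj = 0; kj < kw; ++kj) {
        int wlo, whi; tap_range(W, Wo, stride, padL, kj, wlo, whi);
        for (int ki = 0; ki < kh; ++ki) {
          int hlo, hhi; tap_range(H, Ho, stride, padT, ki, hlo, hhi);
          double wv = pw[(R_xlen_t)ki + kh * ((R_xlen_t)kj + (R_xlen_t)kw * c)];
          if (wv == 0.0) continue;
          for (int wo = wlo; wo < whi; ++wo) {
            int wi = wo * stride - padL + kj;
            double* yrow = yc + (R_xlen_t)Ho * wo;
            const double* xrow = xc + (R_xlen_t)H * wi - padT + ki;
            for (int ho = hlo; ho < hhi; ++ho)
              yrow[ho] += wv * xrow[(R_xlen_t)ho * stride];
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int padT, int padB, int padL, int padR) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((R_xlen_t)H * W * C * B), gw((R_xlen_t)kh * kw * C), gb(C);
  gx.attr("dim") = xd; gw.attr("dim") = wd;
  const double* px = x.begin(); const double* pw = w.begin(); const double* pg = gy.begin();
  double* pgx = gx.begin(); double* pgw = gw.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gc = pg + IDX(0, 0, c, b, Ho, Wo, C);
      const double* xc = px + IDX(0, 0, c, b, H, W, C);
      double* gxc = pgx + IDX(0, 0, c, b, H, W, C);
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) gb[c] += gc[i];
      for (int kj = 0; kj < kw; ++kj) {
        int wlo, whi; tap_range(W, Wo, stride, padL, kj, wlo, whi);
        for (int ki = 0; ki < kh; ++ki) {
          int hlo, hhi; tap_range(H, Ho, stride, padT, ki, hlo, hhi);
          R_xlen_t wi2 = (R_xlen_t)ki + kh * ((R_xlen_t)kj + (R_xlen_t)kw * c);
          double wv = pw[wi2], acc = 0.0;
          for (int wo = wlo; wo < whi; ++wo) {
            int wi = wo * stride - padL + kj;
            const double* grow = gc + (R_xlen_t)Ho * wo;
            const double* xrow = xc + (R_xlen_t)H * wi - padT + ki;
            double* gxrow = gxc + (R_xlen_t)H * wi - padT + ki;
            for (int ho = hlo; ho < hhi; ++ho) {
              double g = grow[ho];
              gxrow[(R_xlen_t)ho * stride] += g * wv;
              acc += g * xrow[(R_xlen_t)ho * stride];
            }
          }
          pgw[wi2] += acc;
        }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with optional ceil mode (partial windows at the bottom/right
// edge).  Returns pooled map and 1-based flat argmax indices into x.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, bool ceil_mode) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho, Wo;
  if (ceil_mode) {
    Ho = (H - k + stride - 1) / stride + 1;
    Wo = (W - k + stride - 1) / stride + 1;
    if ((Ho - 1) * stride >= H) Ho--;
    if ((Wo - 1) * stride >= W) Wo--;
  } else {
    Ho = (H - k) / stride + 1;
    Wo = (W - k) / stride + 1;
  }
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * C * B));
  IntegerVector idx(Rcpp::no_init((R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* px = x.begin(); double* py = y.begin(); int* pi = idx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride, w0 = wo * stride;
          double best = R_NegInf; R_xlen_t bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = w0 + kj; if (wi >= W) break;
            for (int ki = 0; ki < k; ++ki) {
              int hi = h0 + ki; if (hi >= H) break;
              R_xlen_t xi = IDX(hi, wi, c, b, H, W, C);
              if (px[xi] > best) { best = px[xi]; bi = xi; }
            }
          }
          R_xlen_t yi = IDX(ho, wo, c, b, Ho, Wo, C);
          py[yi] = best; pi[yi] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  const double* pg = gy.begin(); const int* pi = idx.begin(); double* pgx = gx.begin();
  R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) pgx[pi[i] - 1] += pg[i];
  return gx;
}

// Bilinear resize with half-pixel centre alignment; edge-clamped sampling.
// [[Rcpp::export]]
NumericVector bilinear_resize_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* px = x.begin(); double* py = y.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    double ws = (wo + 0.5) * sw - 0.5;
    int w0 = (int)std::floor(ws); double fw = ws - w0;
    int w0c = std::min(std::max(w0, 0), W - 1), w1c = std::min(std::max(w0 + 1, 0), W - 1);
    for (int ho = 0; ho < Ho; ++ho) {
      double hs = (ho + 0.5) * sh - 0.5;
      int h0 = (int)std::floor(hs); double fh = hs - h0;
      int h0c = std::min(std::max(h0, 0), H - 1), h1c = std::min(std::max(h0 + 1, 0), H - 1);
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < C; ++c) {
          double v = (1 - fh) * (1 - fw) * px[IDX(h0c, w0c, c, b, H, W, C)] +
                     (1 - fh) * fw       * px[IDX(h0c, w1c, c, b, H, W, C)] +
                     fh * (1 - fw)       * px[IDX(h1c, w0c, c, b, H, W, C)] +
                     fh * fw             * px[IDX(h1c, w1c, c, b, H, W, C)];
          py[IDX(ho, wo, c, b, Ho, Wo, C)] = v;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_resize_bwd_cpp(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* pg = gy.begin(); double* pgx = gx.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    double ws = (wo + 0.5) * sw - 0.5;
    int w0 = (int)std::floor(ws); double fw = ws - w0;
    int w0c = std::min(std::max(w0, 0), W - 1), w1c = std::min(std::max(w0 + 1, 0), W - 1);
    for (int ho = 0; ho < Ho; ++ho) {
      double hs = (ho + 0.5) * sh - 0.5;
      int h0 = (int)std::floor(hs); double fh = hs - h0;
      int h0c = std::min(std::max(h0, 0), H - 1), h1c = std::min(std::max(h0 + 1, 0), H - 1);
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < C; ++c) {
          double g = pg[IDX(ho, wo, c, b, Ho, Wo, C)];
          pgx[IDX(h0c, w0c, c, b, H, W, C)] += (1 - fh) * (1 - fw) * g;
          pgx[IDX(h0c, w1c, c, b, H, W, C)] += (1 - fh) * fw * g;
          pgx[IDX(h1c, w0c, c, b, H, W, C)] += fh * (1 - fw) * g;
          pgx[IDX(h1c, w1c, c, b, H, W, C)] += fh * fw * g;
        }
    }
  }
  return gx;
}

static inline int reflect_index(int i, int n) {
  // reflect without repeating the border sample (a b c b a ...)
  if (n == 1) return 0;
  int p = 2 * (n - 1);
  i = ((i % p) + p) % p;
  return i < n ? i : p - i;
}

// Rotate a 2-D image (matrix) about its centre by `deg` degrees
// (counter-clockwise), bilinear sampling with reflected borders.
// [[Rcpp::export]]
NumericMatrix rotate_bilinear_cpp(NumericMatrix x, double deg) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  double th = deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      // inverse map: output (i,j) samples input at rotation by -deg
      double dy = i - cy, dx = j - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      int h0 = (int)std::floor(sy), w0 = (int)std::floor(sx);
      double fh = sy - h0, fw = sx - w0;
      int h0r = reflect_index(h0, H), h1r = reflect_index(h0 + 1, H);
      int w0r = reflect_index(w0, W), w1r = reflect_index(w0 + 1, W);
      y(i, j) = (1 - fh) * (1 - fw) * x(h0r, w0r) +
                (1 - fh) * fw       * x(h0r, w1r) +
                fh * (1 - fw)       * x(h1r, w0r) +
                fh * fw             * x(h1r, w1r);
    }
  return y;
}
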