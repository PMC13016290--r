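// Compiled numerical primitives for the conv-net engine and metrics.
// Feature maps use column-major arrays with dim (H, W, N, C):
// x[h + H*(w + W*(n + N*c))].

#include <Rcpp.h>
#include <cmath>
#include <cfloat>

using namespace Rcpp;

static inline int idx4(int h, int w, int n, int c, int H, int W, int N) {
  return h + H * (w + W * (n + N * c));
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int R = Ho * Wo * N;
  NumericMatrix M(R, k * k * C);
  double *m = M.begin();
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        double *col = m + (size_t)q * R;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            const bool wok = (w >= 0 && w < W);
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + ki;
              const int r = ho + Ho * (wo + Wo * n);
              col[r] = (wok && h >= 0 && h < H)
                         ? px[idx4(h, w, n, c, H, W, N)] : 0.0;
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix M, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int R = Ho * Wo * N;
  NumericVector out((size_t)H * W * N * C);
  double *po = out.begin();
  const double *m = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        const double *col = m + (size_t)q * R;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              po[idx4(h, w, n, c, H, W, N)] += col[ho + Ho * (wo + Wo * n)];
            }
          }
        }
      }
    }
  }
  return out;
}

// Depthwise convolution, stride 1, "same" padding (k odd).
// w has dim (k, k, C), b length C.
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  NumericVector y((size_t)H * W * N * C);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *wc = pw + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double acc = pb[c];
          for (int kj = 0; kj < k; ++kj) {
            const int ww = wo - p + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hh = ho - p + ki;
              if (hh < 0 || hh >= H) continue;
              acc += wc[ki + k * kj] * px[idx4(hh, ww, n, c, H, W, N)];
            }
          }
          py[idx4(ho, wo, n, c, H, W, N)] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_bwd_x(NumericVector dy, NumericVector w,
                               int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  NumericVector dx((size_t)H * W * N * C);
  const double *pd = dy.begin(), *pw = w.begin();
  double *px = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double *wc = pw + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int ww = wo + p - kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hh = ho + p - ki;
              if (hh < 0 || hh >= H) continue;
              acc += wc[ki + k * kj] * pd[idx4(hh, ww, n, c, H, W, N)];
            }
          }
          px[idx4(ho, wo, n, c, H, W, N)] = acc;
        }
      }
    }
  }
  return dx;
}

// Returns list(dw = (k,k,C), db = C)
// [[Rcpp::export]]
List cpp_dwconv_bwd_w(NumericVector x, NumericVector dy,
                      int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  NumericVector dw((size_t)k * k * C), db(C);
  const double *px = x.begin(), *pd = dy.begin();
  double *pdw = dw.begin(), *pdb = db.begin();
  for (int c = 0; c < C; ++c) {
    double *wc = pdw + (size_t)k * k * c;
    double bsum = 0.0;
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const double g = pd[idx4(ho, wo, n, c, H, W, N)];
          bsum += g;
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int ww = wo - p + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hh = ho - p + ki;
              if (hh < 0 || hh >= H) continue;
              wc[ki + k * kj] += g * px[idx4(hh, ww, n, c, H, W, N)];
            }
          }
        }
      }
    }
    pdb[c] = bsum;
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Bilinear x2 upsampling, half-pixel centers (align_corners = FALSE).
// [[Rcpp::export]]
NumericVector cpp_upsample2x_fwd(NumericVector x, int H, int W, int N, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * N * C);
  const double *px = x.begin();
  double *py = y.begin();
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int o = 0; o < Ho; ++o) {
    double s = 0.5 * o - 0.25;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    if (i0 < 0) { i0 = 0; f = 0.0; }
    int i1 = i0 + 1;
    if (i1 > H - 1) { i1 = H - 1; f = 0.0; }
    h0[o] = i0; h1[o] = i1; fh[o] = f;
  }
  for (int o = 0; o < Wo; ++o) {
    double s = 0.5 * o - 0.25;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    if (i0 < 0) { i0 = 0; f = 0.0; }
    int i1 = i0 + 1;
    if (i1 > W - 1) { i1 = W - 1; f = 0.0; }
    w0[o] = i0; w1[o] = i1; fw[o] = f;
  }
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo) {
        const double fwv = fw[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const double fhv = fh[ho];
          const double v00 = px[idx4(h0[ho], w0[wo], n, c, H, W, N)];
          const double v10 = px[idx4(h1[ho], w0[wo], n, c, H, W, N)];
          const double v01 = px[idx4(h0[ho], w1[wo], n, c, H, W, N)];
          const double v11 = px[idx4(h1[ho], w1[wo], n, c, H, W, N)];
          py[idx4(ho, wo, n, c, Ho, Wo, N)] =
            (1 - fhv) * (1 - fwv) * v00 + fhv * (1 - fwv) * v10 +
            (1 - fhv) * fwv * v01 + fhv * fwv * v11;
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bwd(NumericVector dy, int H, int W, int N, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * N * C);
  const double *pd = dy.begin();
  double *px = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo) {
        double s = 0.5 * wo - 0.25;
        int j0 = (int)std::floor(s);
        double fwv = s - j0;
        if (j0 < 0) { j0 = 0; fwv = 0.0; }
        int j1 = j0 + 1;
        if (j1 > W - 1) { j1 = W - 1; fwv = 0.0; }
        for (int ho = 0; ho < Ho; ++ho) {
          double t = 0.5 * ho - 0.25;
          int i0 = (int)std::floor(t);
          double fhv = t - i0;
          if (i0 < 0) { i0 = 0; fhv = 0.0; }
          int i1 = i0 + 1;
          if (i1 > H - 1) { i1 = H - 1; fhv = 0.0; }
          const double g = pd[idx4(ho, wo, n, c, Ho, Wo, N)];
          px[idx4(i0, j0, n, c, H, W, N)] += (1 - fhv) * (1 - fwv) * g;
          px[idx4(i1, j0, n, c, H, W, N)] += fhv * (1 - fwv) * g;
          px[idx4(i0, j1, n, c, H, W, N)] += (1 - fhv) * fwv * g;
          px[idx4(i1, j1, n, c, H, W, N)] += fhv * fwv * g;
        }
      }
  return dx;
}

static inline double cubic_kernel(double t) {
  // Keys cubic, a = -0.5
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample a single 2D matrix (H x W) to (Ho x Wo).
// method: 0 = nearest, 1 = bilinear, 2 = bicubic. Half-pixel centers.
// [[Rcpp::export]]
NumericMatrix cpp_resample2d(NumericMatrix img, int Ho, int Wo, int method) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Ho, Wo);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    const double sx = (wo + 0.5) * sw - 0.5;
    for (int ho = 0; ho < Ho; ++ho) {
      const double sy = (ho + 0.5) * sh - 0.5;
      double v;
      if (method == 0) {
        v = img(clampi((int)std::lround(sy), 0, H - 1),
                clampi((int)std::lround(sx), 0, W - 1));
      } else if (method == 1) {
        int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
        double fy = sy - i0, fx = sx - j0;
        int i0c = clampi(i0, 0, H - 1), i1c = clampi(i0 + 1, 0, H - 1);
        int j0c = clampi(j0, 0, W - 1), j1c = clampi(j0 + 1, 0, W - 1);
        v = (1 - fy) * (1 - fx) * img(i0c, j0c) + fy * (1 - fx) * img(i1c, j0c) +
            (1 - fy) * fx * img(i0c, j1c) + fy * fx * img(i1c, j1c);
      } else {
        int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
        double acc = 0.0;
        for (int dj = -1; dj <= 2; ++dj) {
          const double kx = cubic_kernel(sx - (j0 + dj));
          if (kx == 0.0) continue;
          for (int di = -1; di <= 2; ++di) {
            const double ky = cubic_kernel(sy - (i0 + di));
            if (ky == 0.0) continue;
            acc += kx * ky * img(clampi(i0 + di, 0, H - 1),
                                 clampi(j0 + dj, 0, W - 1));
          }
        }
        v = acc;
      }
      out(ho, wo) = v;
    }
  }
  return out;
}

// Rotate a 2D matrix by angle (degrees, counter-clockwise) about its centre,
// same output size. method: 0 = nearest, 1 = bilinear; fill for out-of-bounds.
// [[Rcpp::export]]
NumericMatrix cpp_rotate2d(NumericMatrix img, double angle, int method,
                           double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      // inverse map: rotate output coordinate by -angle
      const double dy = h - cy, dx = w - cx;
      const double sy = ct * dy + st * dx + cy;
      const double sx = -st * dy + ct * dx + cx;
      double v = fill;
      if (method == 0) {
        const int i = (int)std::lround(sy), j = (int)std::lround(sx);
        if (i >= 0 && i < H && j >= 0 && j < W) v = img(i, j);
      } else {
        const int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
        const double fy = sy - i0, fx = sx - j0;
        if (i0 >= -1 && i0 <= H - 1 && j0 >= -1 && j0 <= W - 1) {
          auto at = [&](int i, int j) {
            return (i >= 0 && i < H && j >= 0 && j < W) ? img(i, j) : fill;
          };
          v = (1 - fy) * (1 - fx) * at(i0, j0) + fy * (1 - fx) * at(i0 + 1, j0) +
              (1 - fy) * fx * at(i0, j0 + 1) + fy * fx * at(i0 + 1, j0 + 1);
        }
      }
      out(h, w) = v;
    }
  }
  return out;
}

// For each row of A (n x d), the Euclidean distance to its nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = DBL_MAX;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int q = 0; q < d; ++q) {
        const double diff = A(i, q) - B(j, q);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
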