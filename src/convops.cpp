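// Batched 2-D convolution and pooling primitives for the layer graph.
// Layout: activations are (H, W, C, N) column-major arrays; kernels are
// (kh, kw, Cin, Cout). The convolution is the flipped-kernel (true
// convolution) orientation: y[i,j] = sum_{d,k} x[i-d, j-k] w[d,k], realised
// as cross-correlation with the kernel reversed in both spatial dims.
// im2col + GEMM keeps the inner loops in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Build the im2col patch matrix for one sample.
// P is (Ho*Wo) x (kh*kw*Cin); rows enumerate output positions
// (column-major over Ho then Wo), columns enumerate (kh, kw, Cin).
// Kernel flipping is folded into the patch gather so that GEMM with the
// unflipped kernel matrix realises true convolution.
static void im2col_flip(const double *x, int H, int W, int C,
                        int kh, int kw, int sh, int sw, int ph, int pw,
                        int Ho, int Wo, arma::mat &P) {
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        // flipped kernel: weight index (di,dj) touches input offset
        // (kh-1-di, kw-1-dj)
        const int oi = kh - 1 - di, oj = kw - 1 - dj;
        const int col = di + kh * (dj + kw * c);
        double *pcol = P.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int jin = wo * sw - pw + oj;
          const bool jok = (jin >= 0 && jin < W);
          const double *xcol = jok ? x + (size_t)(c * W + jin) * H : nullptr;
          for (int ho = 0; ho < Ho; ++ho) {
            const int iin = ho * sh - ph + oi;
            double v = 0.0;
            if (jok && iin >= 0 && iin < H) v = xcol[iin];
            pcol[ho + Ho * wo] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back to the input (col2im).
static void col2im_flip(const arma::mat &dP, int H, int W, int C,
                        int kh, int kw, int sh, int sw, int ph, int pw,
                        int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int oi = kh - 1 - di, oj = kw - 1 - dj;
        const int col = di + kh * (dj + kw * c);
        const double *pcol = dP.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int jin = wo * sw - pw + oj;
          if (jin < 0 || jin >= W) continue;
          double *xcol = dx + (size_t)(c * W + jin) * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int iin = ho * sh - ph + oi;
            if (iin < 0 || iin >= H) continue;
            xcol[iin] += pcol[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int sh, int sw, int ph, int pw) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4); get_dims4(w, dw4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int kh = dw4[0], kw = dw4[1], Cin = dw4[2], Cout = dw4[3];
  if (Cin != C) stop("input channels (%d) do not match kernel channels (%d)", C, Cin);
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel does not fit input under this padding");

  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat P(Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_flip(x.begin() + (size_t)n * H * W * C, H, W, C,
                kh, kw, sh, sw, ph, pw, Ho, Wo, P);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    Y = P * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int sh, int sw, int ph, int pw,
                   bool need_dx, bool need_dw) {
  int dx4[4], dw4[4], dy4[4];
  get_dims4(x, dx4); get_dims4(w, dw4); get_dims4(dy, dy4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int kh = dw4[0], kw = dw4[1], Cout = dw4[3];
  const int Ho = dy4[0], Wo = dy4[1];

  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, Cout, false, true);
  NumericVector dxv, dwv;
  NumericVector dbv(Cout);
  if (need_dx) { dxv = NumericVector((size_t)H * W * C * N);
    dxv.attr("dim") = IntegerVector::create(H, W, C, N); }
  if (need_dw) { dwv = NumericVector((size_t)kh * kw * C * Cout);
    dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout); }
  arma::mat dWm(need_dw ? dwv.begin() : nullptr, kh * kw * C, Cout, false, true);

  arma::mat P(Ho * Wo, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    if (need_dw) {
      im2col_flip(x.begin() + (size_t)n * H * W * C, H, W, C,
                  kh, kw, sh, sw, ph, pw, Ho, Wo, P);
      dWm += P.t() * dY;
      for (int co = 0; co < Cout; ++co) dbv[co] += arma::accu(dY.col(co));
    }
    if (need_dx) {
      arma::mat dP = dY * Wm.t();
      col2im_flip(dP, H, W, C, kh, kw, sh, sw, ph, pw, Ho, Wo,
                  dxv.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Non-overlapping pooling with floor semantics (trailing remainder dropped).
// kind: 0 = average, 1 = max. For max pooling the argmax (1-based linear
// index into the input sample block) is recorded for winner-take-all
// unpooling; ties break to the lowest index.
// [[Rcpp::export]]
List cpp_pool_fw(NumericVector x, int kh, int kw, int kind) {
  int d4[4];
  get_dims4(x, d4);
  const int H = d4[0], W = d4[1], C = d4[2], N = d4[3];
  const int Ho = H / kh, Wo = W / kw;
  if (Ho < 1 || Wo < 1) stop("pool window larger than input");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector sw_(kind == 1 ? (size_t)Ho * Wo * C * N : (size_t)0);
  const double inv = 1.0 / (kh * kw);
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)n * H * W * C;
    double *ys = y.begin() + (size_t)n * Ho * Wo * C;
    int *ss = (kind == 1) ? sw_.begin() + (size_t)n * Ho * Wo * C : nullptr;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = (kind == 1) ? -std::numeric_limits<double>::infinity() : 0.0;
          int arg = -1;
          for (int dj = 0; dj < kw; ++dj) {
            for (int di = 0; di < kh; ++di) {
              const int ii = ho * kh + di, jj = wo * kw + dj;
              const size_t idx = (size_t)ii + (size_t)H * (jj + (size_t)W * c);
              const double v = xs[idx];
              if (kind == 1) {
                if (v > acc) { acc = v; arg = (int)idx; }
              } else acc += v;
            }
          }
          const size_t oidx = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * c);
          ys[oidx] = (kind == 1) ? acc : acc * inv;
          if (kind == 1) ss[oidx] = arg + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["switches"] = sw_);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bw(NumericVector dy, IntegerVector switches,
                          int H, int W, int C, int kh, int kw, int kind) {
  int d4[4];
  get_dims4(dy, d4);
  const int Ho = d4[0], Wo = d4[1], N = d4[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (kh * kw);
  for (int n = 0; n < N; ++n) {
    const double *dys = dy.begin() + (size_t)n * Ho * Wo * C;
    double *dxs = dx.begin() + (size_t)n * H * W * C;
    const int *ss = (kind == 1) ? switches.begin() + (size_t)n * Ho * Wo * C : nullptr;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t oidx = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * c);
          const double g = dys[oidx];
          if (kind == 1) {
            dxs[ss[oidx] - 1] += g;
          } else {
            const double gs = g * inv;
            for (int dj = 0; dj < kw; ++dj)
              for (int di = 0; di < kh; ++di)
                dxs[(size_t)(ho * kh + di) +
                    (size_t)H * ((wo * kw + dj) + (size_t)W * c)] += gs;
          }
        }
      }
    }
  }
  return dx;
}
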