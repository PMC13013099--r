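// Hot-path tensor kernels for the SNN forward/backward passes.
//
// Tensors follow R's column-major array layout with dims (N, H, W, C): the
// batch index is fastest, so the innermost loops run over n and vectorize.
// Convolutions are same-padding, stride 1, computed by direct loops — at
// the small spatial sizes these networks use, direct accumulation beats
// im2col + BLAS because it allocates nothing.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// x: (N,H,W,Cin); Wk: (k,k,Cin,Cout); bias: Cout. Returns y: (N,H,W,Cout).
// For each kernel tap the update is one contiguous axpy over the (n, h)
// plane (columns shifted by dh are still contiguous in memory), so the
// inner loops vectorize over runs of length about N * H.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const NumericVector& Wk,
                           const NumericVector& bias,
                           int N, int H, int Wd, int Cin, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)N * H;
  NumericVector y((R_xlen_t)N * H * Wd * Cout);
  const double* xp = x.begin();
  const double* wp = Wk.begin();
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double* yco = yp + plane * Wd * co;
    const double b = bias[co];
    if (b != 0.0) for (R_xlen_t i = 0; i < plane * Wd; ++i) yco[i] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xci = xp + plane * Wd * ci;
      for (int dw = 0; dw < k; ++dw) {
        const int wlo = std::max(0, pad - dw), whi = std::min(Wd, Wd + pad - dw);
        for (int dh = 0; dh < k; ++dh) {
          const double wv = wp[dh + k * (dw + k * (ci + (R_xlen_t)Cin * co))];
          if (wv == 0.0) continue;
          const int hoff = dh - pad;
          const R_xlen_t lo = (R_xlen_t)N * std::max(0, -hoff);
          const R_xlen_t hi = (R_xlen_t)N * std::min(H, H - hoff);
          for (int w = wlo; w < whi; ++w) {
            double* yrow = yco + plane * w;
            const double* xrow = xci + plane * (w + dw - pad) + (R_xlen_t)N * hoff;
            for (R_xlen_t i = lo; i < hi; ++i) yrow[i] += wv * xrow[i];
          }
        }
      }
    }
  }
  return y;
}

// Gradients of the convolution. dy: (N,H,W,Cout). Returns list with
// gW (k,k,Cin,Cout), gb (Cout) and, when need_dx, dx (N,H,W,Cin).
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericVector& dy, const NumericVector& x,
                  const NumericVector& Wk,
                  int N, int H, int Wd, int Cin, int k, int Cout,
                  bool need_dx) {
  const int pad = (k - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)N * H;
  NumericVector gW((R_xlen_t)k * k * Cin * Cout);
  NumericVector gb(Cout);
  NumericVector dx(need_dx ? (R_xlen_t)N * H * Wd * Cin : 0);
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  const double* wp = Wk.begin();
  double* gwp = gW.begin();
  double* dxp = dx.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* dyco = dyp + plane * Wd * co;
    double gbacc = 0.0;
    for (R_xlen_t i = 0; i < plane * Wd; ++i) gbacc += dyco[i];
    gb[co] = gbacc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xci = xp + plane * Wd * ci;
      double* dxci = dxp + plane * Wd * ci;
      for (int dw = 0; dw < k; ++dw) {
        const int wlo = std::max(0, pad - dw), whi = std::min(Wd, Wd + pad - dw);
        for (int dh = 0; dh < k; ++dh) {
          const R_xlen_t woff = dh + k * (dw + k * (ci + (R_xlen_t)Cin * co));
          const double wv = wp[woff];
          const int hoff = dh - pad;
          const R_xlen_t lo = (R_xlen_t)N * std::max(0, -hoff);
          const R_xlen_t hi = (R_xlen_t)N * std::min(H, H - hoff);
          double acc = 0.0;
          for (int w = wlo; w < whi; ++w) {
            const double* dyrow = dyco + plane * w;
            const double* xrow = xci + plane * (w + dw - pad) + (R_xlen_t)N * hoff;
            if (need_dx) {
              double* dxrow = dxci + plane * (w + dw - pad) + (R_xlen_t)N * hoff;
              for (R_xlen_t i = lo; i < hi; ++i) {
                acc += xrow[i] * dyrow[i];
                dxrow[i] += wv * dyrow[i];
              }
            } else {
              for (R_xlen_t i = lo; i < hi; ++i) acc += xrow[i] * dyrow[i];
            }
          }
          gwp[woff] += acc;
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb, _["dx"] = dx);
}

// Max pooling (pool size = stride = s) with argmax bookkeeping.
// x: (N,H,W,C) -> y: (N,H/s,W/s,C); amax holds the winning linear index
// (1-based, into x) per pooled cell.
// [[Rcpp::export]]
List cpp_pool_fwd(const NumericVector& x, int N, int H, int Wd, int C, int s) {
  const int Ho = H / s, Wo = Wd / s;
  NumericVector y((R_xlen_t)N * Ho * Wo * C);
  IntegerVector amax((R_xlen_t)N * Ho * Wo * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t yoff = (R_xlen_t)N * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c));
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int dw = 0; dw < s; ++dw) {
            for (int dh = 0; dh < s; ++dh) {
              const R_xlen_t xi = n + (R_xlen_t)N * ((ho * s + dh) +
                (R_xlen_t)H * ((wo * s + dw) + (R_xlen_t)Wd * c));
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          yp[yoff + n] = best;
          ap[yoff + n] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["amax"] = amax);
}

// Scatter pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector cpp_pool_bwd(const NumericVector& dy, const IntegerVector& amax,
                           R_xlen_t in_len) {
  NumericVector dx(in_len);
  const double* dyp = dy.begin();
  const int* ap = amax.begin();
  double* dxp = dx.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ap[i] - 1] += dyp[i];
  return dx;
}
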