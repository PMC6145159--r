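#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
#include <cstring>
using namespace Rcpp;

// Shared im2col into a caller-provided buffer: rows = k*k*C ordered
// (kh, kw, c), cols = oH*oW*B ordered (oh, ow, b).  Zero padding.
static void fill_col(const double *xp, double *cp, int H, int W, int C,
                     int B, int k, int stride, int pad, int oH, int oW) {
  R_xlen_t rows = (R_xlen_t)k * k * C;
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        R_xlen_t ccol = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * b);
        double *dst = cp + rows * ccol;
        int h0 = oh * stride - pad, w0 = ow * stride - pad;
        if (h0 >= 0 && w0 >= 0 && h0 + k <= H && w0 + k <= W) {
          for (int c = 0; c < C; ++c) {
            const double *src = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * b)
                                + h0;
            double *dc = dst + (R_xlen_t)k * k * c;
            for (int kw = 0; kw < k; ++kw)
              memcpy(dc + (R_xlen_t)k * kw, src + (R_xlen_t)H * (w0 + kw),
                     k * sizeof(double));
          }
        } else {
          for (int c = 0; c < C; ++c) {
            const double *src = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
            for (int kw = 0; kw < k; ++kw) {
              int w = w0 + kw;
              for (int kh = 0; kh < k; ++kh) {
                int h = h0 + kh;
                dst[kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c)] =
                  (h >= 0 && h < H && w >= 0 && w < W)
                    ? src[h + (R_xlen_t)H * w] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Fused convolution + bias + ReLU for a batch.
// x: array (H, W, C, B); Wm: (Cout x k*k*C) weight matrix; bias: length Cout.
// Returns the activated output as an array (oH, oW, Cout, B).
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wm,
                           NumericVector bias, int H, int W, int C, int B,
                           int k, int stride, int pad, int oH, int oW) {
  int Cout = Wm.nrow();
  int K = Wm.ncol();
  R_xlen_t N = (R_xlen_t)oH * oW * B;
  std::vector<double> col((R_xlen_t)K * N);
  fill_col(x.begin(), col.data(), H, W, C, B, k, stride, pad, oH, oW);
  std::vector<double> outm((R_xlen_t)Cout * N);
  {
    const double one = 1.0, zero = 0.0;
    int m = Cout, n = (int)N, kk = K;
    F77_CALL(dgemm)("N", "N", &m, &n, &kk, &one, Wm.begin(), &m,
                    col.data(), &kk, &zero, outm.data(), &m FCONE FCONE);
  }
  NumericVector out(Rcpp::no_init((R_xlen_t)oH * oW * Cout * B));
  double *op = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        R_xlen_t n = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * b);
        const double *src = outm.data() + (R_xlen_t)Cout * n;
        for (int c = 0; c < Cout; ++c) {
          double v = src[c] + bias[c];
          op[oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW *
              (c + (R_xlen_t)Cout * b))] = v > 0.0 ? v : 0.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oH, oW, Cout, B);
  return out;
}

// Backward pass of the fused layer.  `out` is the forward ReLU output
// (its positivity pattern is the activation mask), `dout` the gradient
// w.r.t. it, both (oH, oW, Cout, B).  Returns list(dW, db, dx); dx is
// omitted when want_dx is false (first layer).
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericMatrix Wm, NumericVector out,
                  NumericVector dout, int H, int W, int C, int B,
                  int k, int stride, int pad, int oH, int oW,
                  bool want_dx) {
  int Cout = Wm.nrow();
  int K = Wm.ncol();
  R_xlen_t N = (R_xlen_t)oH * oW * B;
  std::vector<double> col((R_xlen_t)K * N);
  fill_col(x.begin(), col.data(), H, W, C, B, k, stride, pad, oH, oW);

  // masked gradient reordered to (Cout x N)
  std::vector<double> dm((R_xlen_t)Cout * N);
  NumericVector db(Cout);
  const double *mp = out.begin(), *dp = dout.begin();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        R_xlen_t n = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * b);
        double *dst = dm.data() + (R_xlen_t)Cout * n;
        for (int c = 0; c < Cout; ++c) {
          R_xlen_t i = oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW *
                         (c + (R_xlen_t)Cout * b));
          double g = mp[i] > 0.0 ? dp[i] : 0.0;
          dst[c] = g;
          db[c] += g;
        }
      }
    }
  }

  NumericMatrix dW(Cout, K);
  {
    const double one = 1.0, zero = 0.0;
    int m = Cout, n = K, kk = (int)N;
    F77_CALL(dgemm)("N", "T", &m, &n, &kk, &one, dm.data(), &m,
                    col.data(), &n, &zero, dW.begin(), &m FCONE FCONE);
  }

  List res = List::create(Named("W") = dW, Named("b") = db);
  if (want_dx) {
    std::vector<double> dcol((R_xlen_t)K * N);
    const double one = 1.0, zero = 0.0;
    int m = K, n = (int)N, kk = Cout;
    F77_CALL(dgemm)("T", "N", &m, &n, &kk, &one, Wm.begin(), &kk,
                    dm.data(), &kk, &zero, dcol.data(), &m FCONE FCONE);
    NumericVector dx((R_xlen_t)H * W * C * B);  // zero-filled: accumulated
    double *xp = dx.begin();
    for (int b = 0; b < B; ++b) {
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          R_xlen_t ccol = (R_xlen_t)oh + (R_xlen_t)oH *
                          (ow + (R_xlen_t)oW * b);
          const double *src = dcol.data() + (R_xlen_t)K * ccol;
          int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int c = 0; c < C; ++c) {
            double *dst = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
            for (int kw = 0; kw < k; ++kw) {
              int w = w0 + kw;
              if (w < 0 || w >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int h = h0 + kh;
                if (h < 0 || h >= H) continue;
                dst[h + (R_xlen_t)H * w] +=
                  src[kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c)];
              }
            }
          }
        }
      }
    }
    dx.attr("dim") = IntegerVector::create(H, W, C, B);
    res["dx"] = dx;
  }
  return res;
}
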