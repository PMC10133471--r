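// Fused im2col + BLAS kernels for the grouped 1D convolutions.
//
// Feature cubes are stored as R arrays (C, Min, L, B) in column-major
// order. For each EEG channel the sliding windows (kernel length k,
// given stride, zero padding padl) are unrolled into a reusable
// (Min*k) x (Lout*B) buffer and multiplied against that channel's
// weight matrix with dgemm; the backward pass regathers the same
// columns and applies the exact adjoint (scatter-add). The temporal
// (channel-shared) convolution reuses these kernels with Min = 1 and
// one weight slice replicated per channel.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// gather channel c of x (C, Min, L, B) into cols (Min*k, Lout*B)
static void gather_channel(const double* x, int C, int Min, int L, int B,
                           int c, int k, int stride, int padl, int Lout,
                           double* cols) {
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * C * Min * L;
    for (int l = 0; l < Lout; ++l) {
      double* col = cols + ((R_xlen_t)l + (R_xlen_t)b * Lout) * Min * k;
      const int start = l * stride - padl;
      for (int kk = 0; kk < k; ++kk) {
        const int pos = start + kk;
        double* cs = col + (R_xlen_t)kk * Min;
        if (pos < 0 || pos >= L) {
          for (int j = 0; j < Min; ++j) cs[j] = 0.0;
        } else {
          const double* xs = xb + (R_xlen_t)pos * C * Min + c;
          for (int j = 0; j < Min; ++j) cs[j] = xs[(R_xlen_t)j * C];
        }
      }
    }
  }
}

// scatter-add the adjoint of gather_channel
static void scatter_channel(double* dx, int C, int Min, int L, int B,
                            int c, int k, int stride, int padl, int Lout,
                            const double* dcols) {
  for (int b = 0; b < B; ++b) {
    double* xb = dx + (R_xlen_t)b * C * Min * L;
    for (int l = 0; l < Lout; ++l) {
      const double* col = dcols + ((R_xlen_t)l + (R_xlen_t)b * Lout) * Min * k;
      const int start = l * stride - padl;
      for (int kk = 0; kk < k; ++kk) {
        const int pos = start + kk;
        if (pos < 0 || pos >= L) continue;
        double* xs = xb + (R_xlen_t)pos * C * Min + c;
        const double* cs = col + (R_xlen_t)kk * Min;
        for (int j = 0; j < Min; ++j) xs[(R_xlen_t)j * C] += cs[j];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gconv_fwd(NumericVector x, IntegerVector dims,
                        NumericVector Wm, NumericVector bias, int k,
                        int stride, int padl, int Lout) {
  const int C = dims[0], Min = dims[1], L = dims[2], B = dims[3];
  const int Mout = Wm.size() / (Min * k) / C;
  const int N = Lout * B, K = Min * k;
  NumericVector y((R_xlen_t)C * Mout * Lout * B);
  std::vector<double> cols((size_t)K * N), yc((size_t)Mout * N);
  const double one = 1.0, zero = 0.0;
  for (int c = 0; c < C; ++c) {
    gather_channel(x.begin(), C, Min, L, B, c, k, stride, padl, Lout,
                   cols.data());
    const double* Wc = Wm.begin() + (R_xlen_t)c * K * Mout;
    F77_CALL(dgemm)("T", "N", &Mout, &N, &K, &one, Wc, &K, cols.data(), &K,
                    &zero, yc.data(), &Mout FCONE FCONE);
    const double* bc = bias.begin() + (R_xlen_t)c * Mout;
    // write into (C, Mout, Lout, B)
    for (int n = 0; n < N; ++n) {
      double* yp = y.begin() + (R_xlen_t)c + (R_xlen_t)n * C * Mout;
      const double* ys = yc.data() + (size_t)n * Mout;
      for (int i = 0; i < Mout; ++i) yp[(R_xlen_t)i * C] = ys[i] + bc[i];
    }
  }
  y.attr("dim") = IntegerVector::create(C, Mout, Lout, B);
  return y;
}

// [[Rcpp::export]]
List gconv_bwd(NumericVector x, IntegerVector dims, NumericVector Wm,
               NumericVector dy, int k, int stride, int padl, int Lout) {
  const int C = dims[0], Min = dims[1], L = dims[2], B = dims[3];
  const int Mout = Wm.size() / (Min * k) / C;
  const int N = Lout * B, K = Min * k;
  NumericVector dx((R_xlen_t)C * Min * L * B);
  NumericVector dWm((R_xlen_t)K * Mout * C);
  NumericVector db((R_xlen_t)Mout * C);
  std::vector<double> cols((size_t)K * N), dyc((size_t)Mout * N),
      dcols((size_t)K * N);
  const double one = 1.0, zero = 0.0;
  for (int c = 0; c < C; ++c) {
    // extract channel slice of dy (C, Mout, Lout, B) -> (Mout, N)
    double* dbc = db.begin() + (R_xlen_t)c * Mout;
    for (int n = 0; n < N; ++n) {
      const double* dp = dy.begin() + (R_xlen_t)c + (R_xlen_t)n * C * Mout;
      double* ds = dyc.data() + (size_t)n * Mout;
      for (int i = 0; i < Mout; ++i) {
        ds[i] = dp[(R_xlen_t)i * C];
        dbc[i] += ds[i];
      }
    }
    gather_channel(x.begin(), C, Min, L, B, c, k, stride, padl, Lout,
                   cols.data());
    // dW_c = cols %*% t(dyc)
    F77_CALL(dgemm)("N", "T", &K, &Mout, &N, &one, cols.data(), &K,
                    dyc.data(), &Mout, &zero,
                    dWm.begin() + (R_xlen_t)c * K * Mout, &K FCONE FCONE);
    // dcols = W_c %*% dyc
    F77_CALL(dgemm)("N", "N", &K, &N, &Mout, &one,
                    Wm.begin() + (R_xlen_t)c * K * Mout, &K, dyc.data(),
                    &Mout, &zero, dcols.data(), &K FCONE FCONE);
    scatter_channel(dx.begin(), C, Min, L, B, c, k, stride, padl, Lout,
                    dcols.data());
  }
  dx.attr("dim") = dims;
  dWm.attr("dim") = IntegerVector::create(K, Mout, C);
  db.attr("dim") = IntegerVector::create(Mout, C);
  return List::create(_["dx"] = dx, _["dW"] = dWm, _["db"] = db);
}
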