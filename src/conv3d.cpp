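#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Index plumbing for batched 3-D convolutions on cubic grids.
//
// Activation layout: a (C * D^3) x B matrix; row index = v * C + c with the
// channel fastest and voxel linear index v = (z * D + y) * D + x.  With this
// layout the reshape between the GEMM view (C x D^3*B) and the activation
// view is free (no copy), so conv and transposed conv reduce to
// im2col/col2im plus matrix products done in R via BLAS.

// [[Rcpp::export(name = ".conv_index_cpp")]]
IntegerVector conv_index_cpp(int d_in, int k, int stride, int pad) {
  int d_out = (d_in + 2 * pad - k) / stride + 1;
  if (d_out < 1) stop("conv geometry: non-positive output side");
  const int k3 = k * k * k;
  const R_xlen_t n_out = (R_xlen_t)d_out * d_out * d_out;
  IntegerVector idx(n_out * k3);
  R_xlen_t q = 0;
  for (int oz = 0; oz < d_out; ++oz)
    for (int oy = 0; oy < d_out; ++oy)
      for (int ox = 0; ox < d_out; ++ox) {
        for (int tz = 0; tz < k; ++tz)
          for (int ty = 0; ty < k; ++ty)
            for (int tx = 0; tx < k; ++tx) {
              int iz = oz * stride - pad + tz;
              int iy = oy * stride - pad + ty;
              int ix = ox * stride - pad + tx;
              bool in = iz >= 0 && iz < d_in && iy >= 0 && iy < d_in &&
                        ix >= 0 && ix < d_in;
              idx[q++] = in ? ((iz * d_in + iy) * d_in + ix) : -1;
            }
      }
  idx.attr("d_out") = d_out;
  return idx;
}

// X: (Cin * Di^3) x B  ->  P: (Cin * k^3) x (Do^3 * B), sample-major columns.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(const NumericMatrix &X, const IntegerVector &idx,
                         int cin, int k3, int n_out) {
  const int B = X.ncol();
  NumericMatrix P(cin * k3, (R_xlen_t)n_out * B);
  const double *xp = X.begin();
  double *pp = P.begin();
  const R_xlen_t xcolstride = X.nrow();
  const R_xlen_t pcolstride = P.nrow();
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (R_xlen_t)b * xcolstride;
    for (int o = 0; o < n_out; ++o) {
      double *pc = pp + ((R_xlen_t)b * n_out + o) * pcolstride;
      const int *ib = &idx[(R_xlen_t)o * k3];
      for (int t = 0; t < k3; ++t) {
        int v = ib[t];
        if (v < 0) {
          for (int c = 0; c < cin; ++c) pc[t * cin + c] = 0.0;
        } else {
          const double *src = xb + (R_xlen_t)v * cin;
          for (int c = 0; c < cin; ++c) pc[t * cin + c] = src[c];
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col: scatter-add patches back onto the input grid.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(const NumericMatrix &P, const IntegerVector &idx,
                         int cin, int k3, int n_out, int di3, int B) {
  NumericMatrix X(cin * di3, B);
  const double *pp = P.begin();
  double *xp = X.begin();
  const R_xlen_t xcolstride = X.nrow();
  const R_xlen_t pcolstride = P.nrow();
  for (int b = 0; b < B; ++b) {
    double *xb = xp + (R_xlen_t)b * xcolstride;
    for (int o = 0; o < n_out; ++o) {
      const double *pc = pp + ((R_xlen_t)b * n_out + o) * pcolstride;
      const int *ib = &idx[(R_xlen_t)o * k3];
      for (int t = 0; t < k3; ++t) {
        int v = ib[t];
        if (v < 0) continue;
        double *dst = xb + (R_xlen_t)v * cin;
        for (int c = 0; c < cin; ++c) dst[c] += pc[t * cin + c];
      }
    }
  }
  return X;
}
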