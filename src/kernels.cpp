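// Fused elementwise kernels for the STA-CNN hot path. All heavy linear
// algebra stays in R (BLAS); these kernels only avoid the large temporary
// allocations R-level broadcasting would create on multi-megabyte feature
// maps. Layout convention matches the R side: feature maps are (C, B, T, F)
// column-major, i.e. channel fastest, filter slowest.

#include <Rcpp.h>
#include <cmath>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Training repeatedly allocates and frees ~50 MB feature maps; with glibc's
// default mmap threshold every such buffer is a fresh mmap whose pages the
// kernel must zero on each batch. Raising the threshold to 128 MB lets the
// allocator reuse those buffers (roughly halving the cost of a training
// step) while still returning continuous-recording-sized blocks to the OS.
// No-op on other C libraries.
// [[Rcpp::init]]
void stacnn_tune_malloc(DllInfo* dll) {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 128 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 64 * 1024 * 1024);
#endif
}

// ELU (alpha = 1) and its derivative in one pass.
// [[Rcpp::export]]
List cpp_elu(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(no_init(n)), d(no_init(n));
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (v > 0) {
      y[i] = v;
      d[i] = 1.0;
    } else {
      double e = std::exp(v);
      y[i] = e - 1.0;
      d[i] = e;
    }
  }
  return List::create(_["Y"] = y, _["D"] = d);
}

// y[c + C*j] = x[c + C*j] * a[j]  (broadcast a over the leading dim)
// [[Rcpp::export]]
NumericVector cpp_scale_cols(NumericVector x, NumericVector a, int C) {
  R_xlen_t m = a.size();
  NumericVector y(no_init(x.size()));
  R_xlen_t k = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    double s = a[j];
    for (int c = 0; c < C; ++c, ++k) y[k] = x[k] * s;
  }
  return y;
}

// y[c + C*j] = x[c + C*j] * a[j] + p[j]
// [[Rcpp::export]]
NumericVector cpp_axpb_cols(NumericVector x, NumericVector a,
                            NumericVector p, int C) {
  R_xlen_t m = a.size();
  NumericVector y(no_init(x.size()));
  R_xlen_t k = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    double s = a[j], q = p[j];
    for (int c = 0; c < C; ++c, ++k) y[k] = x[k] * s + q;
  }
  return y;
}

// out[j] = sum_c x[c + C*j] * w[c + C*j]  (fold product over leading dim)
// [[Rcpp::export]]
NumericVector cpp_mul_colsum_groups(NumericVector x, NumericVector w,
                                    int C) {
  R_xlen_t m = x.size() / C;
  NumericVector out(m);
  R_xlen_t k = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    double s = 0.0;
    for (int c = 0; c < C; ++c, ++k) s += x[k] * w[k];
    out[j] = s;
  }
  return out;
}

// out[j] = sum_c x[c + C*j]
// [[Rcpp::export]]
NumericVector cpp_colsum_groups(NumericVector x, int C) {
  R_xlen_t m = x.size() / C;
  NumericVector out(m);
  R_xlen_t k = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    double s = 0.0;
    for (int c = 0; c < C; ++c, ++k) s += x[k];
    out[j] = s;
  }
  return out;
}

// x viewed as (R, T, F): y[r,t,f] = x[r,t,f] * s[r + R*f]
// [[Rcpp::export]]
NumericVector cpp_scale_rf(NumericVector x, NumericVector s, int R, int T,
                           int F) {
  NumericVector y(no_init(x.size()));
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    const double* sf = &s[(R_xlen_t)R * f];
    for (int t = 0; t < T; ++t)
      for (int r = 0; r < R; ++r, ++k) y[k] = x[k] * sf[r];
  }
  return y;
}

// x viewed as (R, T, F): y[r,t,f] = x[r,t,f] * s[r + R*f] + p[r + R*f]
// [[Rcpp::export]]
NumericVector cpp_axpb_rf(NumericVector x, NumericVector s, NumericVector p,
                          int R, int T, int F) {
  NumericVector y(no_init(x.size()));
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    const double* sf = &s[(R_xlen_t)R * f];
    const double* pf = &p[(R_xlen_t)R * f];
    for (int t = 0; t < T; ++t)
      for (int r = 0; r < R; ++r, ++k) y[k] = x[k] * sf[r] + pf[r];
  }
  return y;
}

// x viewed as (R, T, F): out[r,f] = sum_t x[r,t,f]
// [[Rcpp::export]]
NumericVector cpp_sum_time(NumericVector x, int R, int T, int F) {
  NumericVector out((R_xlen_t)R * F);
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    double* of = &out[(R_xlen_t)R * f];
    for (int t = 0; t < T; ++t)
      for (int r = 0; r < R; ++r, ++k) of[r] += x[k];
  }
  return out;
}

// x viewed as (R, T, F): out[r,f] = sum_t x[r,t,f] * w[r,t,f]
// [[Rcpp::export]]
NumericVector cpp_mul_sum_time(NumericVector x, NumericVector w, int R,
                               int T, int F) {
  NumericVector out((R_xlen_t)R * F);
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    double* of = &out[(R_xlen_t)R * f];
    for (int t = 0; t < T; ++t)
      for (int r = 0; r < R; ++r, ++k) of[r] += x[k] * w[k];
  }
  return out;
}

// per-filter mean and mean of squares: x viewed as (n1, F)
// [[Rcpp::export]]
NumericMatrix cpp_colstats(NumericVector x, double n1d) {
  R_xlen_t n1 = (R_xlen_t)n1d;
  int F = (int)(x.size() / n1);
  NumericMatrix out(F, 2);
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    double s = 0.0, sq = 0.0;
    for (R_xlen_t i = 0; i < n1; ++i, ++k) {
      double v = x[k];
      s += v;
      sq += v * v;
    }
    out(f, 0) = s / n1;
    out(f, 1) = sq / n1;
  }
  return out;
}

// batch-norm affine: x viewed as (n1, F); y = x * a[f] + b[f]
// [[Rcpp::export]]
NumericVector cpp_affine_cols(NumericVector x, NumericVector a,
                              NumericVector b, double n1d) {
  R_xlen_t n1 = (R_xlen_t)n1d;
  int F = a.size();
  NumericVector y(no_init(x.size()));
  R_xlen_t k = 0;
  for (int f = 0; f < F; ++f) {
    double af = a[f], bf = b[f];
    for (R_xlen_t i = 0; i < n1; ++i, ++k) y[k] = x[k] * af + bf;
  }
  return y;
}

// batch-norm backward in two fused passes; x viewed as (n1, F).
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector dy, NumericVector m,
                     NumericVector inv_sd, NumericVector gamma, double n1d,
                     bool train) {
  R_xlen_t n1 = (R_xlen_t)n1d;
  int F = m.size();
  NumericVector dx(no_init(x.size())), dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    R_xlen_t off = (R_xlen_t)n1 * f;
    double mf = m[f], isd = inv_sd[f];
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < n1; ++i) {
      double xh = (x[off + i] - mf) * isd;
      sg += dy[off + i] * xh;
      sb += dy[off + i];
    }
    dgamma[f] = sg;
    dbeta[f] = sb;
    double g = gamma[f];
    if (train) {
      double c1 = g * isd;
      double c2 = g * isd / n1;
      for (R_xlen_t i = 0; i < n1; ++i) {
        double xh = (x[off + i] - mf) * isd;
        dx[off + i] = c1 * dy[off + i] - c2 * (xh * sg + sb);
      }
    } else {
      double c1 = g * isd;
      for (R_xlen_t i = 0; i < n1; ++i) dx[off + i] = c1 * dy[off + i];
    }
  }
  return List::create(_["dX"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Return freed heap memory to the OS. Long training runs fragment the
// allocator arena with ~25-50 MB feature-map buffers; calling this at phase
// boundaries keeps the resident set bounded without giving up buffer reuse
// inside a phase. No-op off glibc.
// [[Rcpp::export]]
void cpp_malloc_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// inverted dropout using R's RNG (reproducible under set.seed)
// [[Rcpp::export]]
List cpp_dropout(NumericVector x, double p) {
  R_xlen_t n = x.size();
  NumericVector y(no_init(n)), mask(no_init(n));
  double scale = 1.0 / (1.0 - p);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double u = R::unif_rand();
    double m = (u >= p) ? scale : 0.0;
    mask[i] = m;
    y[i] = x[i] * m;
  }
  return List::create(_["Y"] = y, _["mask"] = mask);
}
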