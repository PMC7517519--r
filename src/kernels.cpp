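// Hot-path kernels for the training loop. All activations use the flat
// time-major layout documented in R/encoder.R: an (N*T) x C matrix whose
// row (t-1)*N + n holds series n at time t, so every kernel below is a
// contiguous single-pass operation.

#include <Rcpp.h>
using namespace Rcpp;

// im2col for valid 1D convolution in the time-major layout: block j of
// the output is rows [j*n, j*n + n*t_out) of the input, one copy per
// input channel.
// [[Rcpp::export]]
NumericMatrix im2col_tm(const NumericMatrix& a, int n, int t_out, int k) {
  const int c_in = a.ncol();
  const int len = n * t_out;
  NumericMatrix m(len, c_in * k);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < c_in; ++c) {
      const double* src = &a(j * n, c);
      double* dst = &m(0, j * c_in + c);
      std::copy(src, src + len, dst);
    }
  }
  return m;
}

// Adjoint of im2col_tm: scatter-add the gradient blocks back onto the
// input rows.
// [[Rcpp::export]]
NumericMatrix col2im_tm(const NumericMatrix& dm, int n, int t_in,
                        int t_out, int k, int c_in) {
  const int len = n * t_out;
  NumericMatrix da(n * t_in, c_in);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < c_in; ++c) {
      const double* src = &dm(0, j * c_in + c);
      double* dst = &da(j * n, c);
      for (int i = 0; i < len; ++i) dst[i] += src[i];
    }
  }
  return da;
}

// In-place rectifier. Only ever called on a freshly allocated product
// that has a single reference, so mutating the underlying storage is
// safe.
// [[Rcpp::export]]
void relu_inplace(NumericMatrix z) {
  double* p = z.begin();
  const R_xlen_t len = z.size();
  for (R_xlen_t i = 0; i < len; ++i) {
    if (p[i] < 0) p[i] = 0;
  }
}

// In-place rectifier gradient: zero dz wherever the cached post-relu
// activation is zero. Same single-reference caveat as relu_inplace.
// [[Rcpp::export]]
void relu_mask_inplace(NumericMatrix dz, const NumericMatrix& act) {
  double* p = dz.begin();
  const double* a = act.begin();
  const R_xlen_t len = dz.size();
  for (R_xlen_t i = 0; i < len; ++i) {
    if (a[i] <= 0) p[i] = 0;
  }
}

// In-place per-channel bias add on a fresh (n*t) x c product.
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix z, const NumericVector& b) {
  const int nc = z.ncol();
  const R_xlen_t nr = z.nrow();
  for (int c = 0; c < nc; ++c) {
    double* p = &z(0, c);
    const double bc = b[c];
    for (R_xlen_t i = 0; i < nr; ++i) p[i] += bc;
  }
}

// Temporal mean over the t time blocks of the flat layout: (n*t) x c ->
// n x c.
// [[Rcpp::export]]
NumericMatrix gap_forward(const NumericMatrix& a, int n, int t) {
  const int c_out = a.ncol();
  NumericMatrix out(n, c_out);
  for (int c = 0; c < c_out; ++c) {
    const double* src = &a(0, c);
    double* dst = &out(0, c);
    for (int j = 0; j < t; ++j) {
      const R_xlen_t off = (R_xlen_t)j * n;
      for (int i = 0; i < n; ++i) dst[i] += src[off + i];
    }
    for (int i = 0; i < n; ++i) dst[i] /= t;
  }
  return out;
}

// Backward of the temporal mean: replicate dfeat (n x d) across t time
// blocks, dividing by t.
// [[Rcpp::export]]
NumericMatrix gap_backward(const NumericMatrix& dfeat, int t) {
  const int n = dfeat.nrow(), d = dfeat.ncol();
  NumericMatrix out(n * t, d);
  for (int c = 0; c < d; ++c) {
    const double* src = &dfeat(0, c);
    double* dst = &out(0, c);
    for (int j = 0; j < t; ++j) {
      for (int i = 0; i < n; ++i) dst[(R_xlen_t)j * n + i] = src[i] / t;
    }
  }
  return out;
}

// Fused additive-attention score pass: given the affine projections
// s1 = H Wg' and s2 = H Wgp' (both R x d_a), computes the gate
// pre-activation pre[i, j] = ba + sum_k wa_k * tanh(s1[i,k] + s2[j,k] +
// bg_k) together with the per-k tanh sheets needed by the backward
// pass, in a single sweep.
// [[Rcpp::export]]
List attention_pre_sheets(const NumericMatrix& s1, const NumericMatrix& s2,
                          const NumericVector& bg, const NumericVector& wa,
                          double ba) {
  const int r = s1.nrow(), d_a = s1.ncol();
  NumericMatrix pre(r, r);
  std::fill(pre.begin(), pre.end(), ba);
  List sheets(d_a);
  for (int k = 0; k < d_a; ++k) {
    NumericMatrix g(r, r);
    const double* a = &s1(0, k);
    const double* b = &s2(0, k);
    const double bk = bg[k], wk = wa[k];
    double* gp = g.begin();
    double* pp = pre.begin();
    for (int j = 0; j < r; ++j) {
      const double bj = b[j] + bk;
      const R_xlen_t off = (R_xlen_t)j * r;
      for (int i = 0; i < r; ++i) {
        const double v = std::tanh(a[i] + bj);
        gp[off + i] = v;
        pp[off + i] += wk * v;
      }
    }
    sheets[k] = g;
  }
  return List::create(_["pre"] = pre, _["sheets"] = sheets);
}

// Backward of the fused score pass: accumulates the gradients of the
// affine projections and of wa, bg from dpre and the cached sheets.
// [[Rcpp::export]]
List attention_bwd_sheets(const NumericMatrix& dpre, const List& sheets,
                          const NumericVector& wa) {
  const int r = dpre.nrow();
  const int d_a = sheets.size();
  NumericMatrix ds1(r, d_a), ds2(r, d_a);
  NumericVector dwa(d_a), dbg(d_a);
  const double* dp = dpre.begin();
  for (int k = 0; k < d_a; ++k) {
    NumericMatrix g = sheets[k];
    const double* gp = g.begin();
    const double wk = wa[k];
    double sw = 0, sb = 0;
    double* d1 = &ds1(0, k);
    double* d2 = &ds2(0, k);
    for (int j = 0; j < r; ++j) {
      const R_xlen_t off = (R_xlen_t)j * r;
      double colsum = 0;
      for (int i = 0; i < r; ++i) {
        const double gv = gp[off + i];
        const double dpv = dp[off + i];
        sw += dpv * gv;
        const double tk = wk * dpv * (1.0 - gv * gv);
        d1[i] += tk;
        colsum += tk;
      }
      d2[j] = colsum;
      sb += colsum;
    }
    dwa[k] = sw;
    dbg[k] = sb;
  }
  return List::create(_["ds1"] = ds1, _["ds2"] = ds2, _["dwa"] = dwa,
                      _["dbg"] = dbg);
}
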