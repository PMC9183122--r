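// Fused element-wise kernels for the training loop. The matrix products run
// on BLAS from R; these kernels remove the remaining single-pass bottlenecks
// (bias+activation, ReLU backward, dropout masking, Adam updates) that would
// otherwise allocate several large temporaries per mini-batch.

#include <Rcpp.h>
using namespace Rcpp;

// Add a per-column bias and (optionally) apply ReLU, in place. `z` must be a
// freshly allocated matrix (the result of a matrix product), never a vector
// shared with other bindings.
// [[Rcpp::export]]
void cpp_bias_act_inplace(NumericMatrix z, NumericVector b, bool relu) {
  const R_xlen_t n = z.nrow(), f = z.ncol();
  double *pz = REAL(z);
  for (R_xlen_t j = 0; j < f; ++j) {
    const double bj = b[j];
    double *col = pz + j * n;
    if (relu) {
      for (R_xlen_t i = 0; i < n; ++i) {
        double v = col[i] + bj;
        col[i] = v > 0 ? v : 0 * v;  // 0*v, not 0: NaN must propagate
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) col[i] += bj;
    }
  }
}

// dout * (a > 0), one pass, one allocation
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dout, NumericVector a) {
  const R_xlen_t n = dout.size();
  NumericVector dz(n);
  const double *pd = REAL(dout), *pa = REAL(a);
  double *pz = REAL(dz);
  for (R_xlen_t i = 0; i < n; ++i) pz[i] = pa[i] > 0 ? pd[i] : 0;
  dz.attr("dim") = dout.attr("dim");
  return dz;
}

// Inverted dropout using R's RNG stream (so set.seed() governs it): returns
// the masked activations and the mask itself for the backward pass.
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector x, double rate) {
  const R_xlen_t n = x.size();
  NumericVector out(n), mask(n);
  const double keep_scale = 1.0 / (1.0 - rate);
  const double *px = REAL(x);
  double *po = REAL(out), *pm = REAL(mask);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (unif_rand() >= rate) {
      pm[i] = keep_scale;
      po[i] = px[i] * keep_scale;
    }  // else both stay 0
  }
  out.attr("dim") = x.attr("dim");
  mask.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["mask"] = mask);
}

// One Adam update, fully in place: par, m and v are private to the training
// loop (deep-copied on entry / snapshot), so mutation is safe and avoids
// reallocating multi-megabyte weight arrays every batch.
// [[Rcpp::export]]
void cpp_adam_inplace(NumericVector par, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double beta1, double beta2,
                      double eps, double bc1, double bc2) {
  const R_xlen_t n = par.size();
  double *pp = REAL(par), *pm = REAL(m), *pv = REAL(v);
  const double *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1 - beta2) * gi * gi;
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
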