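// Hot inner kernels for surrogate permutation testing.
//
// These exist to keep the per-permutation cost close to the FFT cost: the
// rotation gather, the complex packing for the two-signals-per-transform
// Hilbert trick, and the PLV resultant are single fused passes with one
// allocation each, instead of chains of R-level temporaries.

#include <Rcpp.h>
using namespace Rcpp;

// Rotated copy of a concatenated trial series: within trial j the output is
// amp[(t + cuts[j]) mod trial_len], i.e. the cut-and-swap surrogate.
// [[Rcpp::export]]
NumericVector rotate_trials_cpp(const NumericVector& amp,
                                const IntegerVector& cuts,
                                const int trial_len) {
  const int n_trials = cuts.size();
  NumericVector out(no_init(amp.size()));
  for (int j = 0; j < n_trials; ++j) {
    const int s = j * trial_len;
    const int c = cuts[j];
    const int head = trial_len - c;
    std::copy(amp.begin() + s + c, amp.begin() + s + trial_len,
              out.begin() + s);
    std::copy(amp.begin() + s, amp.begin() + s + c,
              out.begin() + s + head);
  }
  return out;
}

// Block of rotated copies as columns of a matrix (for batched GLM fits).
// [[Rcpp::export]]
NumericMatrix rotate_trials_block_cpp(const NumericVector& amp,
                                      const IntegerMatrix& cuts,
                                      const int trial_len) {
  const int n = amp.size();
  const int n_trials = cuts.nrow();
  const int m = cuts.ncol();
  NumericMatrix out(no_init(n, m));
  for (int p = 0; p < m; ++p) {
    double* col = &out(0, p);
    for (int j = 0; j < n_trials; ++j) {
      const int s = j * trial_len;
      const int c = cuts(j, p);
      const int head = trial_len - c;
      std::copy(amp.begin() + s + c, amp.begin() + s + trial_len, col + s);
      std::copy(amp.begin() + s, amp.begin() + s + c, col + s + head);
    }
  }
  return out;
}

// One elementwise IRLS sweep for the gamma/log GLM: writes the working
// response Z = Eta + Y * exp(-Eta) - 1 into the preallocated matrix Z and
// returns colSums(Y * exp(-Eta)), the data-dependent part of the deviance.
// [[Rcpp::export]]
NumericVector irls_gamma_sweep_cpp(const NumericMatrix& Y,
                                   const NumericMatrix& Eta,
                                   NumericMatrix Z) {
  const int n = Y.nrow(), m = Y.ncol();
  NumericVector ratio_sum(m);
  for (int j = 0; j < m; ++j) {
    const double* y = &Y(0, j);
    const double* e = &Eta(0, j);
    double* z = &Z(0, j);
    double acc = 0;
    for (int t = 0; t < n; ++t) {
      const double r = y[t] * std::exp(-e[t]);
      acc += r;
      z[t] = e[t] + r - 1.0;
    }
    ratio_sum[j] = acc;
  }
  return ratio_sum;
}

// Pack two real series into one complex vector (a1 + i a2).
// [[Rcpp::export]]
ComplexVector pack_complex_cpp(const NumericVector& a1,
                               const NumericVector& a2) {
  const int n = a1.size();
  ComplexVector out(no_init(n));
  for (int t = 0; t < n; ++t) {
    out[t].r = a1[t];
    out[t].i = a2[t];
  }
  return out;
}

// Analytic-signal spectral mask applied to a packed spectrum: positive
// frequencies doubled, negative zeroed, DC and Nyquist kept.
// [[Rcpp::export]]
ComplexVector analytic_mask_apply_cpp(const ComplexVector& spec) {
  const int n = spec.size();
  ComplexVector out(no_init(n));
  const int half = n / 2;
  out[0] = spec[0];
  const int pos_end = (n % 2 == 0) ? half - 1 : half;
  for (int k = 1; k <= pos_end; ++k) {
    out[k].r = 2.0 * spec[k].r;
    out[k].i = 2.0 * spec[k].i;
  }
  if (n % 2 == 0) out[half] = spec[half];
  for (int k = half + 1; k < n; ++k) {
    out[k].r = 0.0;
    out[k].i = 0.0;
  }
  return out;
}

// PLV resultants for a packed surrogate pair.  `w` is ifft(mask * fft(a1 +
// i a2)) = z1 + i z2 with z_j the analytic signal of a_j, so H{a1} = Im(w) -
// a2 and H{a2} = a1 - Re(w).  Each PLV is |mean exp(i(theta_l - theta_u))|
// with exp(-i theta_u) = (a - i h)/|z|; everything reduces to four real
// accumulators over one pass.
// [[Rcpp::export]]
NumericVector plv_pair_cpp(const ComplexVector& w,
                           const NumericVector& a1,
                           const NumericVector& a2,
                           const NumericVector& cos_t,
                           const NumericVector& sin_t) {
  const int n = w.size();
  const Rcomplex* wp = reinterpret_cast<const Rcomplex*>(w.begin());
  const double* p1 = a1.begin();
  const double* p2 = a2.begin();
  const double* pc = cos_t.begin();
  const double* ps = sin_t.begin();
  const double tiny = std::numeric_limits<double>::min();
  double re1 = 0, im1 = 0, re2 = 0, im2 = 0;
  for (int t = 0; t < n; ++t) {
    const double h1 = wp[t].i - p2[t];
    const double h2 = p1[t] - wp[t].r;
    const double u1 = 1.0 / (std::sqrt(p1[t] * p1[t] + h1 * h1) + tiny);
    const double u2 = 1.0 / (std::sqrt(p2[t] * p2[t] + h2 * h2) + tiny);
    re1 += (pc[t] * p1[t] + ps[t] * h1) * u1;
    im1 += (ps[t] * p1[t] - pc[t] * h1) * u1;
    re2 += (pc[t] * p2[t] + ps[t] * h2) * u2;
    im2 += (ps[t] * p2[t] - pc[t] * h2) * u2;
  }
  return NumericVector::create(std::sqrt(re1 * re1 + im1 * im1) / n,
                               std::sqrt(re2 * re2 + im2 * im2) / n);
}

// Single-series PLV resultant from the analytic signal's parts.
// [[Rcpp::export]]
double plv_single_cpp(const NumericVector& a, const NumericVector& h,
                      const NumericVector& cos_t,
                      const NumericVector& sin_t) {
  const int n = a.size();
  const double tiny = std::numeric_limits<double>::min();
  double re = 0, im = 0;
  for (int t = 0; t < n; ++t) {
    const double u = 1.0 / (std::sqrt(a[t] * a[t] + h[t] * h[t]) + tiny);
    re += (cos_t[t] * a[t] + sin_t[t] * h[t]) * u;
    im += (sin_t[t] * a[t] - cos_t[t] * h[t]) * u;
  }
  return std::sqrt(re * re + im * im) / n;
}

// Rotate two trials-series and pack them as one complex vector in a single
// pass (the input to the paired Hilbert transform).
// [[Rcpp::export]]
ComplexVector rotate_pack_cpp(const NumericVector& amp,
                              const IntegerVector& cuts1,
                              const IntegerVector& cuts2,
                              const int trial_len) {
  const int n_trials = cuts1.size();
  const int n = amp.size();
  ComplexVector out(no_init(n));
  Rcomplex* op = reinterpret_cast<Rcomplex*>(out.begin());
  const double* ap = amp.begin();
  for (int j = 0; j < n_trials; ++j) {
    const int s = j * trial_len;
    const int c1 = cuts1[j], c2 = cuts2[j];
    for (int t = 0; t < trial_len; ++t) {
      int t1 = t + c1; if (t1 >= trial_len) t1 -= trial_len;
      int t2 = t + c2; if (t2 >= trial_len) t2 -= trial_len;
      op[s + t].r = ap[s + t1];
      op[s + t].i = ap[s + t2];
    }
  }
  return out;
}

// PLV resultants for a packed surrogate pair, reading the rotated series
// straight from the packed input `g` (real part = first series, imaginary
// part = second).
// [[Rcpp::export]]
NumericVector plv_pair_g_cpp(const ComplexVector& w,
                             const ComplexVector& g,
                             const NumericVector& cos_t,
                             const NumericVector& sin_t) {
  const int n = w.size();
  const Rcomplex* wp = reinterpret_cast<const Rcomplex*>(w.begin());
  const Rcomplex* gp = reinterpret_cast<const Rcomplex*>(g.begin());
  const double* pc = cos_t.begin();
  const double* ps = sin_t.begin();
  const double tiny = std::numeric_limits<double>::min();
  double re1 = 0, im1 = 0, re2 = 0, im2 = 0;
  for (int t = 0; t < n; ++t) {
    const double a1 = gp[t].r, a2 = gp[t].i;
    const double h1 = wp[t].i - a2;
    const double h2 = a1 - wp[t].r;
    const double u1 = 1.0 / (std::sqrt(a1 * a1 + h1 * h1) + tiny);
    const double u2 = 1.0 / (std::sqrt(a2 * a2 + h2 * h2) + tiny);
    re1 += (pc[t] * a1 + ps[t] * h1) * u1;
    im1 += (ps[t] * a1 - pc[t] * h1) * u1;
    re2 += (pc[t] * a2 + ps[t] * h2) * u2;
    im2 += (ps[t] * a2 - pc[t] * h2) * u2;
  }
  return NumericVector::create(std::sqrt(re1 * re1 + im1 * im1) / n,
                               std::sqrt(re2 * re2 + im2 * im2) / n);
}
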