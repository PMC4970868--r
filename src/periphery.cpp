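#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Auditory periphery core. One gammatone channel is a cascade of `order`
// complex one-pole filters (all-pole gammatone approximation); the real part
// is half-wave rectified, power-law compressed and smoothed by a second-order
// low-pass biquad whose coefficients are supplied by the caller
// (signal::butter at 1 kHz). The biquad can undershoot slightly on
// transients, so the output is clamped at zero to keep activations
// non-negative; clamping preserves the a^0.4 homogeneity of the stage.

static void gammatone_channel(const NumericVector &wave, double fs, double cf,
                              int order, double bw_factor, double compress_exp,
                              const NumericVector &lp_b, const NumericVector &lp_a,
                              std::vector<double> &out) {
  const int n = wave.size();
  const double erb = 24.7 * (4.37 * cf / 1000.0 + 1.0);
  const double b = bw_factor * erb;
  const double lambda = std::exp(-2.0 * M_PI * b / fs);
  const double theta = 2.0 * M_PI * cf / fs;
  const double ar = lambda * std::cos(theta);
  const double ai = lambda * std::sin(theta);
  const double gain = std::pow(1.0 - lambda, order);

  // one pass over the samples with the cascade states kept in registers
  // (mathematically identical to `order` sequential one-pole passes)
  std::vector<double> sr(order, 0.0), si(order, 0.0);
  for (int k = 0; k < n; ++k) {
    double xr = wave[k], xi = 0.0;
    for (int s = 0; s < order; ++s) {
      double tr = xr + ar * sr[s] - ai * si[s];
      double ti = xi + ar * si[s] + ai * sr[s];
      sr[s] = tr;
      si[s] = ti;
      xr = tr;
      xi = ti;
    }
    double v = gain * xr;
    out[k] = (v > 0.0) ? std::pow(v, compress_exp) : 0.0;
  }
  // low-pass biquad, direct form II transposed; a[0] assumed 1
  double z1 = 0.0, z2 = 0.0;
  for (int k = 0; k < n; ++k) {
    double x = out[k];
    double y = lp_b[0] * x + z1;
    z1 = lp_b[1] * x - lp_a[1] * y + z2;
    z2 = lp_b[2] * x - lp_a[2] * y;
    out[k] = (y > 0.0) ? y : 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cochleogram_cpp(NumericVector wave, double fs, NumericVector cf_hz,
                              int order, double bw_factor, double compress_exp,
                              NumericVector lp_b, NumericVector lp_a) {
  const int n = wave.size();
  const int nch = cf_hz.size();
  NumericMatrix out(nch, n);
  std::vector<double> ch(n);
  for (int c = 0; c < nch; ++c) {
    gammatone_channel(wave, fs, cf_hz[c], order, bw_factor, compress_exp,
                      lp_b, lp_a, ch);
    for (int k = 0; k < n; ++k) out(c, k) = ch[k];
  }
  return out;
}

// argmax with earliest-index tie-break; returns -1 for an all-zero channel
static int first_argmax(const std::vector<double> &x) {
  int idx = 0;
  double best = x.empty() ? 0.0 : x[0];
  for (size_t k = 1; k < x.size(); ++k) {
    if (x[k] > best) {
      best = x[k];
      idx = (int)k;
    }
  }
  if (best == 0.0) return -1;  // all-zero channel (activations are >= 0)
  return idx;
}

// Fused per-echo path used by the template builder: cochleogram -> dechirp
// (align per-channel maxima to the earliest channel argmax, zero-padding at
// the end) -> blank the first `blank_samples` -> mean across channels.
// [[Rcpp::export]]
NumericVector echo_profile_cpp(NumericVector wave, double fs, NumericVector cf_hz,
                               int order, double bw_factor, double compress_exp,
                               NumericVector lp_b, NumericVector lp_a,
                               int blank_samples) {
  const int n = wave.size();
  const int nch = cf_hz.size();
  std::vector<std::vector<double> > cg(nch, std::vector<double>(n));
  std::vector<int> amax(nch);
  int target = -1;
  for (int c = 0; c < nch; ++c) {
    gammatone_channel(wave, fs, cf_hz[c], order, bw_factor, compress_exp,
                      lp_b, lp_a, cg[c]);
    amax[c] = first_argmax(cg[c]);
    if (amax[c] >= 0 && (target < 0 || amax[c] < target)) target = amax[c];
  }
  NumericVector prof(n);
  if (target < 0) return prof;  // silent input -> zero profile
  for (int c = 0; c < nch; ++c) {
    int shift = (amax[c] >= 0) ? (amax[c] - target) : 0;  // silent: unshifted
    for (int k = blank_samples; k < n; ++k) {
      int src = k + shift;
      if (src < n) prof[k] += cg[c][src];
    }
  }
  for (int k = 0; k < n; ++k) prof[k] /= nch;
  return prof;
}

// Accumulate delayed scaled copies of the call into a waveform of length n.
// delay is in samples (0-based index of echo onset).
// [[Rcpp::export]]
NumericVector add_echoes_cpp(int n, NumericVector base, NumericVector call,
                             IntegerVector delay, NumericVector amp) {
  NumericVector w(n);
  for (int k = 0; k < n && k < base.size(); ++k) w[k] = base[k];
  const int nc = call.size();
  for (int i = 0; i < delay.size(); ++i) {
    const int d = delay[i];
    const double a = amp[i];
    for (int k = 0; k < nc; ++k) {
      int idx = d + k;
      if (idx >= 0 && idx < n) w[idx] += a * call[k];
    }
  }
  return w;
}
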