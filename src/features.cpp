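// Core numerical kernels: analytic Morlet CWT via FFT, per-channel
// phase/amplitude feature extraction (MRAS, mean amplitude, reset counts),
// and the swing-magnitude statistic used inside the permutation loop.
// FFTs go through FFTW with cached plans (the transform length is fixed
// within a session, and across sessions of equal length).

#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct PlanPair {
  fftw_plan fwd = nullptr;
  fftw_plan bwd = nullptr;
  fftw_complex* in = nullptr;
  fftw_complex* out = nullptr;
  int n = 0;
};

// One cached in/out buffer + plan pair per transform length.
PlanPair& get_plans(int n) {
  static std::map<int, PlanPair> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  PlanPair p;
  p.n = n;
  p.in = fftw_alloc_complex(n);
  p.out = fftw_alloc_complex(n);
  // invest in planning for the session-scale lengths that are reused
  // thousands of times; planning destroys buffer contents, which is fine
  // here because buffers are filled per call
  unsigned flags = (n >= 4096) ? FFTW_MEASURE : FFTW_ESTIMATE;
  p.fwd = fftw_plan_dft_1d(n, p.in, p.out, FFTW_FORWARD, flags);
  p.bwd = fftw_plan_dft_1d(n, p.in, p.out, FFTW_BACKWARD, flags);
  return cache.emplace(n, p).first->second;
}

// Triangle-wave (symmetric reflection) index mapping into [0, n).
inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  int j = i % p;
  if (j < 0) j += p;
  return (j < n) ? j : p - j;
}

// FFT of the symmetrically extended signal; result stays in a caller-owned
// buffer.
void padded_fft(const double* x, int n, int nfft, int pad_left,
                std::vector<std::complex<double>>& X) {
  PlanPair& p = get_plans(nfft);
  for (int i = 0; i < nfft; ++i) {
    p.in[i][0] = x[reflect_index(i - pad_left, n)];
    p.in[i][1] = 0.0;
  }
  fftw_execute(p.fwd);
  X.resize(nfft);
  std::memcpy(X.data(), p.out, sizeof(fftw_complex) * nfft);
}

// Inverse FFT of X * g (g real, zero on the negative half); result is
// left unnormalised in the plan's output buffer (divide by nfft when
// reading).
fftw_complex* apply_gain_ifft(const std::vector<std::complex<double>>& X,
                              const std::vector<double>& g, int nfft) {
  PlanPair& p = get_plans(nfft);
  for (int k = 0; k < nfft; ++k) {
    p.in[k][0] = X[k].real() * g[k];
    p.in[k][1] = X[k].imag() * g[k];
  }
  fftw_execute(p.bwd);
  return p.out;
}

// Frequency response of the analytic Morlet filter at centre frequency f
// (Hz), L1-style normalisation: a unit-amplitude real sinusoid at f has
// coefficient magnitude 1 at the matching scale.
std::vector<double> morlet_gain(double f, double rate, double omega0,
                                int nfft) {
  std::vector<double> g(nfft, 0.0);
  double s = omega0 / (2.0 * M_PI * f); // scale, seconds
  for (int k = 1; k <= nfft / 2; ++k) {
    double w = 2.0 * M_PI * k * rate / nfft; // rad/s at DFT bin k
    double u = s * w - omega0;
    g[k] = 2.0 * std::exp(-0.5 * u * u);
  }
  return g;
}

} // namespace

// Complex CWT coefficients, one row per analysis frequency, same time
// resolution as the input. Symmetric signal extension to nfft.
// [[Rcpp::export]]
arma::cx_mat cwt_morlet_cpp(const arma::vec& x, const arma::vec& freqs,
                            double rate, double omega0, int nfft) {
  int n = x.n_elem, nf = freqs.n_elem;
  if (nfft < n) stop("nfft smaller than signal length");
  int pad_left = (nfft - n) / 2;
  std::vector<std::complex<double>> X;
  padded_fft(x.memptr(), n, nfft, pad_left, X);
  arma::cx_mat W(nf, n);
  double s = 1.0 / nfft;
  for (int j = 0; j < nf; ++j) {
    std::vector<double> g = morlet_gain(freqs[j], rate, omega0, nfft);
    fftw_complex* y = apply_gain_ifft(X, g, nfft);
    for (int t = 0; t < n; ++t)
      W(j, t) = std::complex<double>(y[pad_left + t][0] * s,
                                     y[pad_left + t][1] * s);
  }
  return W;
}

// One-pass per-session feature extraction. `sig` is channels x samples,
// already bandpassed. Returns per (channel, frequency): time-mean RAS,
// time-mean amplitude, reset-event counts on the trimmed series.
// RAS convention: ras[i] pairs samples (i, i+1) of the trimmed series and
// is aligned to the later sample; detection runs over interior samples.
// [[Rcpp::export]]
List session_features_cpp(const arma::mat& sig, const arma::vec& freqs,
                          double rate, double omega0, int nfft,
                          int trim, double threshold) {
  int nch = sig.n_rows, n = sig.n_cols, nf = freqs.n_elem;
  int T = n - 2 * trim;
  if (T < 3) stop("trimmed series too short for feature extraction");
  if (nfft < n) stop("nfft smaller than signal length");
  int pad_left = (nfft - n) / 2;
  double dt = 1.0 / rate;

  std::vector<std::vector<double>> G(nf);
  for (int j = 0; j < nf; ++j) G[j] = morlet_gain(freqs[j], rate, omega0, nfft);

  arma::mat mras(nch, nf), amp_mean(nch, nf);
  arma::imat counts(nch, nf);
  std::vector<double> amp(T), ras(T - 1);
  std::vector<std::complex<double>> X;
  arma::vec row(n);
  double sc = 1.0 / nfft;

  for (int c = 0; c < nch; ++c) {
    for (int t = 0; t < n; ++t) row[t] = sig(c, t);
    padded_fft(row.memptr(), n, nfft, pad_left, X);
    for (int j = 0; j < nf; ++j) {
      const fftw_complex* y = apply_gain_ifft(X, G[j], nfft) + pad_left + trim;
      double c0 = 2.0 * M_PI * freqs[j] * dt;

      double asum = std::sqrt(y[0][0] * y[0][0] + y[0][1] * y[0][1]) * sc;
      amp[0] = asum;
      double prev_ph = std::atan2(y[0][1], y[0][0]);
      double rsum = 0.0;
      for (int t = 1; t < T; ++t) {
        amp[t] = std::sqrt(y[t][0] * y[t][0] + y[t][1] * y[t][1]) * sc;
        asum += amp[t];
        double ph = std::atan2(y[t][1], y[t][0]);
        double d = ph - prev_ph;
        double dev = d - c0;
        if (dev < -M_PI) d += 2.0 * M_PI;
        else if (dev > M_PI) d -= 2.0 * M_PI;
        ras[t - 1] = d / c0 - 1.0;
        rsum += ras[t - 1];
        prev_ph = ph;
      }
      double mr = rsum / (T - 1);

      int cnt = 0;
      for (int t = 1; t < T - 1; ++t) {
        if (amp[t] < amp[t - 1] && amp[t] < amp[t + 1] &&
            std::fabs(ras[t - 1] - mr) > threshold) ++cnt;
      }
      mras(c, j) = mr;
      amp_mean(c, j) = asum / T;
      counts(c, j) = cnt;
    }
  }
  return List::create(_["mras"] = mras, _["amp_mean"] = amp_mean,
                      _["n_resets"] = counts, _["n_time"] = T,
                      _["duration"] = T * dt);
}

// Swing magnitude of one correlation-vs-frequency curve: collapse equal
// runs (interior plateaus count once), take strict local extrema of the
// condensed sequence, and return the maximum over consecutive extremum
// triples of |centre - mean(flanks)|. Non-finite CCs (constant feature
// columns) are treated as 0. Fewer than 3 extrema -> 0.
static double curve_swing(const double* x, int m) {
  std::vector<double> v;
  v.reserve(m);
  for (int i = 0; i < m; ++i) {
    double xi = std::isfinite(x[i]) ? x[i] : 0.0;
    if (v.empty() || xi != v.back()) v.push_back(xi);
  }
  std::vector<double> peaks;
  int k = (int)v.size();
  for (int j = 1; j + 1 < k; ++j) {
    if ((v[j] > v[j - 1] && v[j] > v[j + 1]) ||
        (v[j] < v[j - 1] && v[j] < v[j + 1]))
      peaks.push_back(v[j]);
  }
  if (peaks.size() < 3) return 0.0;
  double best = 0.0;
  for (size_t j = 1; j + 1 < peaks.size(); ++j) {
    double d = std::fabs(peaks[j] - 0.5 * (peaks[j - 1] + peaks[j + 1]));
    if (d > best) best = d;
  }
  return best;
}

// [[Rcpp::export]]
double curve_swing_cpp(NumericVector x) {
  return curve_swing(REAL(x), x.size());
}

// Max swing over channels for each row of R. Columns of R are ordered
// channel-major: column c*nfreq + j holds (channel c, frequency j).
// [[Rcpp::export]]
NumericVector swing_max_channels_cpp(const NumericMatrix& R, int nfreq, int nchan) {
  if (R.ncol() != nfreq * nchan) stop("column count must equal nfreq * nchan");
  int B = R.nrow();
  NumericVector out(B);
  std::vector<double> curve(nfreq);
  for (int b = 0; b < B; ++b) {
    double best = 0.0;
    for (int c = 0; c < nchan; ++c) {
      for (int j = 0; j < nfreq; ++j) curve[j] = R(b, c * nfreq + j);
      double s = curve_swing(curve.data(), nfreq);
      if (s > best) best = s;
    }
    out[b] = best;
  }
  return out;
}
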