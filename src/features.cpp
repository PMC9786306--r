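// Per-window statistical feature kernels for EMG/IMU channels.
// 17 statistics per channel; definitions documented in the R wrappers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double quantile7(const vec& sorted, double p) {
  // R's default (type 7) quantile on a pre-sorted vector
  const uword n = sorted.n_elem;
  if (n == 1) return sorted(0);
  double h = (n - 1) * p;
  uword lo = (uword)std::floor(h);
  uword hi = lo + 1 < n ? lo + 1 : lo;
  return sorted(lo) + (h - lo) * (sorted(hi) - sorted(lo));
}

// Compute the 17 statistics for one channel window sampled at fs Hz.
static void channel_stats(const vec& x, double fs, double* out) {
  const uword n = x.n_elem;
  double m = mean(x);
  double v = n > 1 ? var(x) : 0.0;            // sample variance (n-1)
  double s = std::sqrt(v);
  double mn = x.min(), mx = x.max();
  vec srt = sort(x);
  double med = quantile7(srt, 0.5);
  double rms = std::sqrt(accu(square(x)) / n);
  double mav = mean(abs(x));
  double iqr = quantile7(srt, 0.75) - quantile7(srt, 0.25);

  // population central moments for skewness g1 and excess kurtosis g2
  vec d = x - m;
  double m2 = accu(square(d)) / n;
  double m3 = accu(pow(d, 3)) / n;
  double m4 = accu(pow(d, 4)) / n;
  double skew = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0;
  double kurt = m2 > 0 ? m4 / (m2 * m2) - 3.0 : 0.0;

  double zc = 0, wl = 0, ssc = 0;
  for (uword i = 1; i < n; ++i) {
    if (x(i - 1) * x(i) < 0) zc += 1;
    wl += std::abs(x(i) - x(i - 1));
  }
  for (uword i = 1; i + 1 < n; ++i)
    if ((x(i) - x(i - 1)) * (x(i + 1) - x(i)) < 0) ssc += 1;
  double energy = accu(square(x));

  // dominant frequency: periodogram bin (DC excluded) with maximal power
  double domfreq = 0.0;
  if (n >= 4) {
    cx_vec ft = fft(x);
    uword kmax = n / 2;
    double best = 0.0;
    for (uword k = 1; k <= kmax; ++k) {
      double p = std::norm(ft(k));
      if (p > best) { best = p; domfreq = k * fs / n; }
    }
    if (best <= 0.0) domfreq = 0.0;
  }

  out[0] = m; out[1] = s; out[2] = v; out[3] = mn; out[4] = mx;
  out[5] = mx - mn; out[6] = med; out[7] = rms; out[8] = mav;
  out[9] = iqr; out[10] = skew; out[11] = kurt; out[12] = zc;
  out[13] = wl; out[14] = ssc; out[15] = energy; out[16] = domfreq;
}

// [[Rcpp::export(name = ".window_stats_cpp")]]
arma::rowvec window_stats_cpp(const arma::mat& block, double fs) {
  rowvec out(block.n_cols * 17);
  for (uword c = 0; c < block.n_cols; ++c)
    channel_stats(block.col(c), fs, out.memptr() + c * 17);
  return out;
}

// Extract the full T x 289 feature matrix from whole-session streams.
// emg: (T*emg_rate) x 8, imu: (T*imu_rate) x 9.
// [[Rcpp::export(name = ".session_features_cpp")]]
arma::mat session_features_cpp(const arma::mat& emg, const arma::mat& imu,
                               int emg_rate, int imu_rate) {
  const uword T = std::min(emg.n_rows / emg_rate, imu.n_rows / imu_rate);
  const uword pe = emg.n_cols * 17, pi = imu.n_cols * 17;
  mat out(T, pe + pi);
  for (uword t = 0; t < T; ++t) {
    const mat eb = emg.rows(t * emg_rate, (t + 1) * emg_rate - 1);
    const mat ib = imu.rows(t * imu_rate, (t + 1) * imu_rate - 1);
    rowvec re(pe), ri(pi);
    for (uword c = 0; c < eb.n_cols; ++c)
      channel_stats(eb.col(c), emg_rate, re.memptr() + c * 17);
    for (uword c = 0; c < ib.n_cols; ++c)
      channel_stats(ib.col(c), imu_rate, ri.memptr() + c * 17);
    out.row(t) = join_rows(re, ri);
  }
  return out;
}
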