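// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void iir_pass(const arma::vec& b, const arma::vec& a, arma::vec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  const int nz = std::max(nb, na) - 1;
  arma::vec z(nz, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      z[k] = bk * xi + z[k + 1] - ak * yi;
    }
    if (nz > 0) {
      double bk = (nz < nb) ? b[nz] : 0.0;
      double ak = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bk * xi - ak * yi;
    }
    x[i] = yi;
  }
}

static void filtfilt_vec(const arma::vec& b, const arma::vec& a, arma::vec& w) {
  iir_pass(b, a, w);
  w = arma::reverse(w);
  iir_pass(b, a, w);
  w = arma::reverse(w);
}

// Frequency-domain synthesis of band-shaped Gaussian noise: independent
// circularly symmetric coefficients at the nonzero bins of `amp_pos` (and
// their negative-frequency partners), one inverse FFT per complex column,
// real and imaginary parts used as two independent real channels.
// [[Rcpp::export]]
arma::mat shaped_noise_cpp(int n, int n_channels, const arma::vec& amp_pos) {
  RNGScope scope;
  const int pc = (n_channels + 1) / 2;
  arma::uvec nz = arma::find(amp_pos > 0);
  arma::cx_mat S(n, pc, arma::fill::zeros);
  const double scale = std::sqrt((double)n);
  for (int c = 0; c < pc; ++c) {
    for (arma::uword j = 0; j < nz.n_elem; ++j) {
      const int k = nz[j] + 1;            // bin index (DC excluded)
      const double a = amp_pos[nz[j]] * scale;
      S(k, c) = std::complex<double>(R::norm_rand() * a, R::norm_rand() * a);
      S(n - k, c) = std::complex<double>(R::norm_rand() * a, R::norm_rand() * a);
    }
  }
  arma::cx_mat x = arma::ifft(S);
  arma::mat out(n, n_channels);
  for (int c = 0; c < n_channels; ++c) {
    const arma::cx_vec& col = x.col(c / 2);
    if (c % 2 == 0) out.col(c) = arma::real(col);
    else out.col(c) = arma::imag(col);
  }
  return out;
}

// Iterative radix-2 Cooley-Tukey FFT (in place) with precomputed twiddles
// and bit-reversal table; used for power-of-two Welch windows where the
// per-call overhead of a general FFT would dominate.
struct Radix2Plan {
  int n;
  std::vector<int> rev;
  std::vector<std::complex<double>> tw;
  explicit Radix2Plan(int n_) : n(n_), rev(n_), tw(n_ / 2) {
    int lg = 0;
    while ((1 << lg) < n) ++lg;
    for (int i = 0; i < n; ++i) {
      int r = 0;
      for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
      rev[i] = r;
    }
    for (int k = 0; k < n / 2; ++k)
      tw[k] = std::polar(1.0, -2.0 * M_PI * k / n);
  }
  void run(std::complex<double>* a) const {
    for (int i = 0; i < n; ++i)
      if (i < rev[i]) std::swap(a[i], a[rev[i]]);
    for (int len = 2; len <= n; len <<= 1) {
      const int half = len >> 1, stride = n / len;
      for (int i = 0; i < n; i += len)
        for (int j = 0; j < half; ++j) {
          const std::complex<double> u = a[i + j];
          const std::complex<double> v = a[i + j + half] * tw[j * stride];
          a[i + j] = u + v;
          a[i + j + half] = u - v;
        }
    }
  }
};

static bool is_pow2(int n) { return n > 0 && (n & (n - 1)) == 0; }

// Per column: zero-phase cascade of two IIR filters (odd-reflection padding
// shared across the cascade), then Welch accumulation: Hann-windowed,
// mean-removed segments of length nw every `step` samples. Returns the raw
// sum over windows of |FFT|^2 at bins 1..floor(nw/2) (DC excluded); the
// caller applies the PSD scaling. Must agree with preprocess + welch_psd
// composed in R (asserted by tests).
// [[Rcpp::export]]
arma::mat filter_welch(const arma::mat& X,
                       const arma::vec& b1, const arma::vec& a1,
                       const arma::vec& b2, const arma::vec& a2,
                       int nw, int step) {
  const int n = X.n_rows, p = X.n_cols;
  const int npad1 = 3 * (std::max(b1.n_elem, a1.n_elem) - 1);
  const int npad2 = 3 * (std::max(b2.n_elem, a2.n_elem) - 1);
  if (n <= std::max(npad1, npad2))
    stop("series too short for zero-phase filtering");
  if (n < nw) stop("input shorter than one Welch window");
  const int nh = nw / 2;
  arma::vec hann(nw);
  for (int i = 0; i < nw; ++i)
    hann[i] = 0.5 - 0.5 * std::cos(2.0 * M_PI * i / (nw - 1));
  const int nwin = (n - nw) / step + 1;
  arma::mat acc(nh, p, arma::fill::zeros);
  arma::vec seg(nw);
  const bool pow2 = is_pow2(nw);
  std::unique_ptr<Radix2Plan> plan(pow2 ? new Radix2Plan(nw) : nullptr);
  std::vector<std::complex<double>> buf(nw);
  for (int c = 0; c < p; ++c) {
    // filter 1 with odd-reflection padding
    arma::vec w1(n + 2 * npad1);
    for (int k = 0; k < npad1; ++k) w1[k] = 2.0 * X(0, c) - X(npad1 - k, c);
    for (int k = 0; k < n; ++k) w1[npad1 + k] = X(k, c);
    for (int k = 0; k < npad1; ++k)
      w1[npad1 + n + k] = 2.0 * X(n - 1, c) - X(n - 2 - k, c);
    filtfilt_vec(b1, a1, w1);
    arma::vec y1 = w1.subvec(npad1, npad1 + n - 1);
    // filter 2
    arma::vec w2(n + 2 * npad2);
    for (int k = 0; k < npad2; ++k) w2[k] = 2.0 * y1[0] - y1[npad2 - k];
    for (int k = 0; k < n; ++k) w2[npad2 + k] = y1[k];
    for (int k = 0; k < npad2; ++k)
      w2[npad2 + n + k] = 2.0 * y1[n - 1] - y1[n - 2 - k];
    filtfilt_vec(b2, a2, w2);
    arma::vec y2 = w2.subvec(npad2, npad2 + n - 1);
    // Welch accumulation; two windows packed per complex FFT (Hermitian
    // split recovers both spectra exactly)
    arma::cx_vec segc(nw);
    for (int wdx = 0; wdx < nwin; wdx += 2) {
      const int s0 = wdx * step;
      const bool paired = (wdx + 1) < nwin;
      const int s1 = paired ? (wdx + 1) * step : 0;
      double mu0 = 0.0, mu1 = 0.0;
      for (int i = 0; i < nw; ++i) mu0 += y2[s0 + i];
      mu0 /= nw;
      if (paired) {
        for (int i = 0; i < nw; ++i) mu1 += y2[s1 + i];
        mu1 /= nw;
        for (int i = 0; i < nw; ++i)
          buf[i] = std::complex<double>((y2[s0 + i] - mu0) * hann[i],
                                        (y2[s1 + i] - mu1) * hann[i]);
        const std::complex<double>* F;
        arma::cx_vec Fa;
        if (pow2) { plan->run(buf.data()); F = buf.data(); }
        else {
          for (int i = 0; i < nw; ++i) segc[i] = buf[i];
          Fa = arma::fft(segc);
          F = Fa.memptr();
        }
        for (int k = 1; k <= nh; ++k) {
          const std::complex<double> Fk = F[k], Fc = std::conj(F[nw - k]);
          const std::complex<double> A = 0.5 * (Fk + Fc);
          const std::complex<double> B =
            std::complex<double>(0.0, -0.5) * (Fk - Fc);
          acc(k - 1, c) += std::norm(A) + std::norm(B);
        }
      } else {
        const std::complex<double>* F;
        arma::cx_vec Fa;
        if (pow2) {
          for (int i = 0; i < nw; ++i)
            buf[i] = std::complex<double>((y2[s0 + i] - mu0) * hann[i], 0.0);
          plan->run(buf.data());
          F = buf.data();
        } else {
          for (int i = 0; i < nw; ++i) seg[i] = (y2[s0 + i] - mu0) * hann[i];
          Fa = arma::fft(seg);
          F = Fa.memptr();
        }
        for (int k = 1; k <= nh; ++k) acc(k - 1, c) += std::norm(F[k]);
      }
    }
  }
  return acc;
}
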