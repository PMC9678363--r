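// Fixed-step third-order Runge-Kutta integrators for the Kuramoto variants.
// Phase state is kept unwrapped internally; wrapped phases are returned.
// Noise is added to the phase after each deterministic step, drawn from R's
// RNG so that set.seed() in R gives bit-identical runs.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// wrap to [0, 2*pi) without std::fmod (keeps the binary free of
// glibc-2.38-versioned math symbols)
static inline double wrap2pi(double x) {
  double w = x - TWO_PI * std::floor(x / TWO_PI);
  if (w >= TWO_PI) w -= TWO_PI;
  if (w < 0.0) w += TWO_PI;
  return w;
}

// gamma density without normalization surprises; t <= 0 -> 0
static inline double gamma_pulse(double t, double a, double b) {
  if (t <= 0.0) return 0.0;
  return R::dgamma(t, a, b, 0);
}

// Classic pairwise coupling: dtheta_i = w_i + (K/N) sum_j sin(theta_j - theta_i)
// Mean-field form:           dtheta_i = w_i + r K sin(Psi - theta_i)
// form: 0 = pairwise, 1 = mean-field. K = 0 reduces both to bare rotators.
// [[Rcpp::export(name = ".kuramoto_continuous")]]
List kuramoto_continuous(NumericVector omega_rad, NumericVector theta0,
                         double K, double dt, int nstep, int form,
                         double noise_sd_step) {
  int N = omega_rad.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  NumericMatrix phases(N, nstep + 1);
  for (int i = 0; i < N; ++i) phases(i, 0) = wrap2pi(th[i]);

  std::vector<double> k1(N), k2(N), k3(N), tmp(N);

  auto deriv = [&](const std::vector<double>& x, std::vector<double>& out) {
    if (K == 0.0 || N == 1) {
      for (int i = 0; i < N; ++i) out[i] = omega_rad[i];
      return;
    }
    if (form == 0) {
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += std::sin(x[j] - x[i]);
        out[i] = omega_rad[i] + (K / N) * s;
      }
    } else {
      double cre = 0.0, cim = 0.0;
      for (int j = 0; j < N; ++j) { cre += std::cos(x[j]); cim += std::sin(x[j]); }
      cre /= N; cim /= N;
      double r = std::sqrt(cre * cre + cim * cim);
      double psi = std::atan2(cim, cre);
      for (int i = 0; i < N; ++i)
        out[i] = omega_rad[i] + r * K * std::sin(psi - x[i]);
    }
  };

  RNGScope scope;
  for (int s = 0; s < nstep; ++s) {
    deriv(th, k1);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] - dt * k1[i] + 2.0 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < N; ++i) {
      th[i] += dt / 6.0 * (k1[i] + 4.0 * k2[i] + k3[i]);
      if (noise_sd_step > 0.0) th[i] += R::norm_rand() * noise_sd_step;
      if (!std::isfinite(th[i]))
        stop("non-finite phase for oscillator %d at step %d", i + 1, s + 1);
      phases(i, s + 1) = wrap2pi(th[i]);
    }
  }
  return List::create(_["phases"] = phases);
}

// Hybrid pulse-coupled model:
//   dtheta_i = w_i + (K/N) * sum_{j != i, j in nbrs(i)} P_j(t) * sign * sin(theta_i)
// P_j(t) is the superposition of gamma pulses triggered at j's upward
// zero-phase crossings. Forcing is tabulated on a half-step grid so the RK3
// stages at t, t+dt/2 and t+dt read consistent values. A refractory of half
// the oscillator's nominal period suppresses noise-induced double crossings.
// topology: 0 = full, 1 = ring, 2 = uncoupled.
// [[Rcpp::export(name = ".kuramoto_pulse")]]
List kuramoto_pulse(NumericVector omega_rad, NumericVector theta0,
                    double K, double dt, int nstep, int topology,
                    double noise_sd_step, double a, double b,
                    double pulse_sign, double kernel_support_s) {
  int N = omega_rad.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  NumericMatrix phases(N, nstep + 1);
  for (int i = 0; i < N; ++i) phases(i, 0) = wrap2pi(th[i]);

  int klen = (int)std::ceil(kernel_support_s / (dt / 2.0));
  int nhalf = 2 * nstep + klen + 4;
  NumericMatrix P(N, nhalf);                   // forcing on half-step grid
  std::vector<std::vector<double>> onsets(N);
  std::vector<double> last_on(N, -1e18), next_cross(N);
  for (int i = 0; i < N; ++i)
    next_cross[i] = std::floor(th[i] / TWO_PI) + 1.0;

  std::vector<double> k1(N), k2(N), k3(N), tmp(N);
  bool coupled = (K != 0.0) && (N > 1) && (topology != 2);

  // forcing received by i at half-grid index m
  auto forcing = [&](int i, int m) -> double {
    if (!coupled) return 0.0;
    double s = 0.0;
    if (topology == 0) {
      for (int j = 0; j < N; ++j) if (j != i) s += P(j, m);
    } else {                                    // ring: two neighbors, periodic
      s += P((i + 1) % N, m);
      s += P((i - 1 + N) % N, m);
    }
    return (K / N) * s;
  };
  auto deriv = [&](const std::vector<double>& x, int m, std::vector<double>& out) {
    for (int i = 0; i < N; ++i)
      out[i] = omega_rad[i] + forcing(i, m) * pulse_sign * std::sin(x[i]);
  };

  RNGScope scope;
  for (int s = 0; s < nstep; ++s) {
    double t0 = s * dt;
    int m0 = 2 * s;
    deriv(th, m0, k1);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    deriv(tmp, m0 + 1, k2);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] - dt * k1[i] + 2.0 * dt * k2[i];
    deriv(tmp, m0 + 2, k3);
    for (int i = 0; i < N; ++i) {
      double thn = th[i] + dt / 6.0 * (k1[i] + 4.0 * k2[i] + k3[i]);
      if (noise_sd_step > 0.0) thn += R::norm_rand() * noise_sd_step;
      if (!std::isfinite(thn))
        stop("non-finite phase for oscillator %d at step %d", i + 1, s + 1);
      double tgt = next_cross[i] * TWO_PI;
      if (thn >= tgt && thn > th[i]) {
        double frac = (tgt - th[i]) / (thn - th[i]);
        double tc = t0 + frac * dt;
        next_cross[i] = std::floor(thn / TWO_PI) + 1.0;
        double refrac = 0.5 * TWO_PI / std::max(std::fabs(omega_rad[i]), 1e-12);
        if (tc - last_on[i] >= refrac) {
          onsets[i].push_back(tc);
          last_on[i] = tc;
          // deposit the pulse on the half-step grid, causally from tc
          int mstart = (int)std::ceil(tc / (dt / 2.0));
          int mend = std::min(mstart + klen, nhalf - 1);
          for (int m = mstart; m <= mend; ++m) {
            double tt = m * (dt / 2.0) - tc;
            P(i, m) += gamma_pulse(tt, a, b);
          }
        }
      }
      th[i] = thn;
      phases(i, s + 1) = wrap2pi(thn);
    }
  }
  List on(N);
  for (int i = 0; i < N; ++i) on[i] = NumericVector(onsets[i].begin(), onsets[i].end());
  return List::create(_["phases"] = phases, _["onsets"] = on);
}
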