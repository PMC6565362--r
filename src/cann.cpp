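// Euler-Maruyama integration loop for the decentralized two-module
// continuous attractor network. Four neuron groups (module 1/2 x
// congruent/opposite) share the layout: columns of the N x 4 state matrices
// are ordered m1c, m1o, m2c, m2o.
//
// Dynamics per group (tau du/dt):
//   -u + Wrc %*% r(same group) + Wrp %*% r(same type, other module) + I
// with divisive normalization r = [u]+^2 / (1 + omega * D),
//   D = gscale * (sum [u_own]+^2 + Jint * sum [u_other-type]+^2),
// and feedforward input
//   I = Iff + sqrt(F * Iff / dt) * xi + Ib + sqrt(F * Ib / dt) * eps,
// where the cue noise xi is shared by the congruent and opposite group of
// the same module and the background noise eps is independent per group.
// Noise values are drawn every step for every source regardless of the
// on/off switches, so toggling one source never perturbs the draws used by
// another.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double relu(double x) { return x > 0.0 ? x : 0.0; }

// Gaussian deviates by Box-Muller over R's uniform stream: deterministic
// given the R seed and considerably faster than the inversion sampler for
// the ~6N draws needed per step.
static void fill_gauss(double *out, int n) {
  int i = 0;
  while (i + 1 < n) {
    double u1 = unif_rand(), u2 = unif_rand();
    double rr = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    out[i++] = rr * std::cos(a);
    out[i++] = rr * std::sin(a);
  }
  if (i < n) {
    double u1 = unif_rand(), u2 = unif_rand();
    out[i] = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
}

// [[Rcpp::export]]
List cann_run_cpp(NumericMatrix u0,        // N x 4 initial synaptic input
                  NumericMatrix Wrc,       // N x N recurrent kernel (incl. gscale)
                  NumericMatrix Wrpc,      // N x N reciprocal, congruent
                  NumericMatrix Wrpo,      // N x N reciprocal, opposite
                  NumericVector Iff1,      // N mean cue drive, module 1 (0 if off)
                  NumericVector Iff2,      // N mean cue drive, module 2
                  double Ib, double fano,
                  double dt, double tau,
                  double omega, double jint, double gscale,
                  int n_burn, int n_sample, int stride,
                  bool cue_noise, bool bg_noise) {
  const int N = u0.nrow();
  const int G = 4;
  std::vector<double> u(N * G), r(N * G), du(N * G);
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < N; ++i) u[g * N + i] = u0(i, g);

  // theta grid (-pi, pi]
  std::vector<double> costh(N), sinth(N);
  for (int i = 0; i < N; ++i) {
    double th = -M_PI + 2.0 * M_PI * (i + 1) / N;
    costh[i] = std::cos(th);
    sinth[i] = std::sin(th);
  }

  // precompute noise amplitude profiles
  const double sdt = std::sqrt(dt);
  std::vector<double> amp_cue1(N), amp_cue2(N);
  for (int i = 0; i < N; ++i) {
    amp_cue1[i] = std::sqrt(fano * Iff1[i]) / sdt;
    amp_cue2[i] = std::sqrt(fano * Iff2[i]) / sdt;
  }
  const double amp_bg = std::sqrt(fano * Ib) / sdt;

  NumericMatrix z(n_sample, G);       // decoded bump position, radians
  NumericMatrix rsum(n_sample, G);    // summed firing rate per group
  NumericMatrix rpeak(n_sample, G);   // max firing rate per group
  NumericMatrix rmean(N, G);          // time-averaged rates over samples
  NumericMatrix rm2(N, G);            // Welford M2 for per-neuron rate SD
  NumericMatrix umean(N, G);

  RNGScope scope;
  const int n_total = n_burn + n_sample * stride;
  int isamp = 0, nacc = 0;
  std::vector<double> xi(2 * N), eps(4 * N);

  for (int t = 0; t < n_total; ++t) {
    // firing rates via divisive normalization; pools shared within module
    double S[4];
    for (int g = 0; g < G; ++g) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) { double v = relu(u[g * N + i]); s += v * v; }
      S[g] = s;
    }
    // D for group g pairs it with the other type in the same module
    const int mate[4] = {1, 0, 3, 2};
    for (int g = 0; g < G; ++g) {
      double D = gscale * (S[g] + jint * S[mate[g]]);
      double denom = 1.0 + omega * D;
      for (int i = 0; i < N; ++i) {
        double v = relu(u[g * N + i]);
        r[g * N + i] = v * v / denom;
      }
    }

    // record after burn-in
    if (t >= n_burn && ((t - n_burn) % stride == 0) && isamp < n_sample) {
      for (int g = 0; g < G; ++g) {
        double cx = 0.0, sx = 0.0, tot = 0.0, pk = 0.0;
        for (int i = 0; i < N; ++i) {
          double ri = r[g * N + i];
          cx += ri * costh[i];
          sx += ri * sinth[i];
          tot += ri;
          if (ri > pk) pk = ri;
        }
        z(isamp, g) = (std::hypot(cx, sx) > 1e-12)
                        ? std::atan2(sx, cx) : NA_REAL;
        rsum(isamp, g) = tot;
        rpeak(isamp, g) = pk;
      }
      ++nacc;
      for (int g = 0; g < G; ++g)
        for (int i = 0; i < N; ++i) {
          double ri = r[g * N + i];
          double d = ri - rmean(i, g);
          rmean(i, g) += d / nacc;
          rm2(i, g) += d * (ri - rmean(i, g));
          umean(i, g) += (u[g * N + i] - umean(i, g)) / nacc;
        }
      ++isamp;
    }

    // draw every active noise source every step; when a source is switched
    // on, all its values are drawn whether or not the other source is on,
    // keeping each source's stream independent of the other's toggle
    const bool draw = cue_noise || bg_noise;
    if (draw) {
      fill_gauss(&xi[0], 2 * N);
      fill_gauss(&eps[0], 4 * N);
    }

    // synaptic drive: recurrent + reciprocal + feedforward.
    // Each kernel matrix is swept once, column-wise (column-major storage),
    // accumulating into every group it serves, so the inner loops vectorize
    // and each matrix is read from memory a single time per step.
    std::fill(du.begin(), du.end(), 0.0);
    {
      const double *Wr = &Wrc(0, 0), *Wc = &Wrpc(0, 0), *Wo = &Wrpo(0, 0);
      for (int j = 0; j < N; ++j) {
        const double *wr = Wr + (size_t)j * N;
        const double r0 = r[j], r1 = r[N + j], r2 = r[2 * N + j],
                     r3 = r[3 * N + j];
        double *d0 = &du[0], *d1 = &du[N], *d2 = &du[2 * N], *d3 = &du[3 * N];
        for (int i = 0; i < N; ++i) {
          const double w = wr[i];
          d0[i] += w * r0; d1[i] += w * r1; d2[i] += w * r2; d3[i] += w * r3;
        }
      }
      for (int j = 0; j < N; ++j) {       // congruent reciprocal: m1c<->m2c
        const double *wc = Wc + (size_t)j * N;
        const double r0 = r[j], r2 = r[2 * N + j];
        double *d0 = &du[0], *d2 = &du[2 * N];
        for (int i = 0; i < N; ++i) {
          const double w = wc[i];
          d0[i] += w * r2; d2[i] += w * r0;
        }
      }
      for (int j = 0; j < N; ++j) {       // opposite reciprocal: m1o<->m2o
        const double *wo = Wo + (size_t)j * N;
        const double r1 = r[N + j], r3 = r[3 * N + j];
        double *d1 = &du[N], *d3 = &du[3 * N];
        for (int i = 0; i < N; ++i) {
          const double w = wo[i];
          d1[i] += w * r3; d3[i] += w * r1;
        }
      }
    }
    for (int g = 0; g < G; ++g) {
      const std::vector<double> &amp = (g < 2) ? amp_cue1 : amp_cue2;
      const NumericVector &Iff = (g < 2) ? Iff1 : Iff2;
      const double *xim = (g < 2) ? &xi[0] : &xi[N];
      const double *epsg = &eps[g * N];
      const double *ug = &u[g * N];
      double *dug = &du[g * N];
      for (int i = 0; i < N; ++i) {
        double I = Iff[i] + Ib;
        if (cue_noise) I += amp[i] * xim[i];
        if (bg_noise) I += amp_bg * epsg[i];
        dug[i] = (dug[i] - ug[i] + I) * dt / tau;
      }
    }
    for (int k = 0; k < N * G; ++k) {
      u[k] += du[k];
      if (!std::isfinite(u[k]))
        stop("network state diverged (non-finite synaptic input) at step %d", t);
    }
  }

  NumericMatrix ufinal(N, G), rsd(N, G);
  // rates for the final state
  {
    double S[4];
    for (int g = 0; g < G; ++g) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) { double v = relu(u[g * N + i]); s += v * v; }
      S[g] = s;
    }
    (void)S;
    for (int g = 0; g < G; ++g)
      for (int i = 0; i < N; ++i) {
        ufinal(i, g) = u[g * N + i];
        rsd(i, g) = (nacc > 1) ? std::sqrt(rm2(i, g) / (nacc - 1)) : NA_REAL;
      }
  }

  return List::create(_["z"] = z, _["rate_sum"] = rsum,
                      _["rate_peak"] = rpeak, _["rate_mean"] = rmean,
                      _["rate_sd"] = rsd, _["u_mean"] = umean,
                      _["u_final"] = ufinal, _["n_samples"] = isamp);
}
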