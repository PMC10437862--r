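#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the delayed, noisy Kuramoto system
//   dtheta_i/dt = 2*pi*omega_i + lambda * sum_{j->i} sin(theta_j(t - d_ji) - theta_i(t))
// with an additive per-step Gaussian phase kick of SD `noise_sd`.
// Phases are kept cumulative (unwrapped). The delay history is a circular
// buffer of max(delay)+1 columns, pre-filled by backward free-running
// extrapolation theta_i(-k dt) = theta0_i - 2*pi*omega_i*k*dt.
// Uses R's RNG stream so results are reproducible under set.seed().
// [[Rcpp::export]]
List kuramoto_euler_cpp(IntegerVector src, IntegerVector dst, IntegerVector delay,
                        NumericVector omega_hz, NumericVector theta0,
                        double lambda, double dt, int n_steps, double noise_sd,
                        int store_stride, bool return_noise) {
  const int n = omega_hz.size();
  const int m = src.size();
  const double two_pi = 2.0 * M_PI;

  int maxd = 0;
  for (int e = 0; e < m; ++e) {
    if (delay[e] < 0) stop("negative delay");
    if (delay[e] > maxd) maxd = delay[e];
  }
  const int H = maxd + 1;

  std::vector<double> omega_rad(n);
  for (int i = 0; i < n; ++i) omega_rad[i] = two_pi * omega_hz[i];

  // circular history buffer: buf[i + n * (t mod H)] = theta_i at step t
  std::vector<double> buf((size_t)n * H);
  for (int k = 0; k <= maxd; ++k) {
    int col = ((0 - k) % H + H) % H;
    for (int i = 0; i < n; ++i)
      buf[(size_t)i + (size_t)n * col] = theta0[i] - omega_rad[i] * k * dt;
  }

  const int n_stored = n_steps / store_stride + 1;
  NumericMatrix theta_out(n, n_stored);
  NumericVector times(n_stored);
  for (int i = 0; i < n; ++i) theta_out(i, 0) = theta0[i];
  times[0] = 0.0;

  std::vector<double> drive(n);
  std::vector<double> noise_rec;
  if (return_noise) noise_rec.reserve((size_t)n * n_steps);

  // per-edge rotating history column: starts at (0 - delay) mod H and
  // advances one column per step, avoiding modulo arithmetic in the loop
  std::vector<int> esrc(m), edst(m), ecol(m);
  for (int e = 0; e < m; ++e) {
    esrc[e] = src[e] - 1;
    edst[e] = dst[e] - 1;
    ecol[e] = ((0 - delay[e]) % H + H) % H;
  }

  int out_col = 1;
  int cur = 0;
  for (int t = 0; t < n_steps; ++t) {
    const double *theta_cur = &buf[(size_t)n * cur];
    std::fill(drive.begin(), drive.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      const double th_j = buf[(size_t)esrc[e] + (size_t)n * ecol[e]];
      drive[edst[e]] += std::sin(th_j - theta_cur[edst[e]]);
      if (++ecol[e] == H) ecol[e] = 0;
    }
    const int nxt = (cur + 1 == H) ? 0 : cur + 1;
    double *theta_nxt = &buf[(size_t)n * nxt];
    if (noise_sd > 0.0) {
      for (int i = 0; i < n; ++i) {
        const double kick = noise_sd * norm_rand();
        if (return_noise) noise_rec.push_back(kick);
        theta_nxt[i] = theta_cur[i] + dt * (omega_rad[i] + lambda * drive[i]) + kick;
      }
    } else {
      for (int i = 0; i < n; ++i)
        theta_nxt[i] = theta_cur[i] + dt * (omega_rad[i] + lambda * drive[i]);
    }
    if ((t + 1) % store_stride == 0 && out_col < n_stored) {
      for (int i = 0; i < n; ++i) {
        const double v = theta_nxt[i];
        if (!R_finite(v))
          stop("non-finite phase at step %d, node %d", t + 1, i + 1);
        theta_out(i, out_col) = v;
      }
      times[out_col] = (t + 1) * dt;
      ++out_col;
    }
    cur = nxt;
  }

  List out = List::create(_["theta"] = theta_out, _["times"] = times);
  if (return_noise) out["noise"] = NumericVector(noise_rec.begin(), noise_rec.end());
  return out;
}
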