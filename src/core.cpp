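// Compiled kernels: steric-clash scan and the 1-D adaptive-biasing-force
// Langevin sampler.  Random numbers come from R's RNG so set.seed() on the
// R side fixes trajectories exactly.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = "has_clash")]]
bool has_clash(const NumericMatrix& xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  // sweep over atoms sorted by z: only pairs closer than the cutoff
  // along z need a full distance check
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return z[a] < z[b]; });
  for (int a = 0; a < n - 1; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < n; ++b) {
      const int j = idx[b];
      const double dz = z[j] - z[i];
      if (dz >= cutoff) break;
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      if (dx * dx + dy * dy + dz * dz < c2) return true;
    }
  }
  return false;
}

// Potential: U(x) = q2*(x-q0)^2 + ((x-q0)/qw)^4 * q4
//                 + sum_i A_i * exp(-(x-m_i)^2 / (2 s_i^2))
static inline double pot_du(double x, double q0, double q2, double q4,
                            double qw, const NumericVector& A,
                            const NumericVector& m, const NumericVector& s) {
  double du = 2.0 * q2 * (x - q0);
  if (q4 != 0.0) du += 4.0 * q4 * std::pow((x - q0) / qw, 3) / qw;
  for (int i = 0; i < A.size(); ++i) {
    const double z = (x - m[i]) / s[i];
    du += -A[i] * z / s[i] * std::exp(-0.5 * z * z);
  }
  return du;
}

// [[Rcpp::export(name = "abf_core")]]
List abf_core(double x0, int n_steps, double lo, double hi, double bin_width,
              double n_min, double dt, double friction, double kT,
              double q0, double q2, double q4, double qw,
              NumericVector A, NumericVector m, NumericVector s,
              int save_stride) {
  const int n_bins = (int)std::lround((hi - lo) / bin_width);
  NumericVector fsum(n_bins);
  NumericVector count(n_bins);
  const int n_save = n_steps / save_stride;
  NumericVector traj(n_save);
  const double D = kT / friction;
  const double noise = std::sqrt(2.0 * D * dt);
  const double span = hi - lo;
  double x = x0;
  RNGScope scope;
  int isave = 0;
  for (int step = 0; step < n_steps; ++step) {
    const double F = -pot_du(x, q0, q2, q4, qw, A, m, s);
    int b = (int)std::floor((x - lo) / bin_width);
    if (b < 0) b = 0;
    if (b >= n_bins) b = n_bins - 1;
    count[b] += 1.0;
    fsum[b] += F;
    double ramp = count[b] / n_min;  // n_min may be +Inf -> ramp 0
    if (ramp > 1.0) ramp = 1.0;
    const double applied = F - ramp * (fsum[b] / count[b]);
    const double dx = applied / friction * dt + noise * norm_rand();
    if (std::fabs(dx) > span) {
      stop("Langevin step larger than the coordinate range at step %d; "
           "use a smaller timestep", step + 1);
    }
    x += dx;
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    if ((step + 1) % save_stride == 0 && isave < n_save) {
      traj[isave++] = x;
    }
  }
  return List::create(_["force_sum"] = fsum, _["count"] = count,
                      _["theta"] = traj, _["x_final"] = x);
}
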