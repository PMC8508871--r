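#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradient of a sum-of-Gaussians landscape: U = offset + sum A_i exp(-(x-c_i)^2 / 2 w_i^2)
static inline double pot_grad(const NumericVector& amp, const NumericVector& cen,
                              const NumericVector& wid, double xi) {
  double g = 0.0;
  const int n = amp.size();
  for (int i = 0; i < n; ++i) {
    const double d = (xi - cen[i]) / wid[i];
    g += -amp[i] * (d / wid[i]) * std::exp(-0.5 * d * d);
  }
  return g;
}

// Restraint gradient.  kind: 0 harmonic, 1 flat-bottom, 2 lower-bound.
// Harmonic: k (xi - c).  Flat-bottom: zero inside |xi-c| <= r, harmonic on the
// excess outside.  Lower-bound: zero beyond |xi-c| >= r, harmonic push-out inside.
static inline double bias_grad(int kind, double center, double k, double r, double xi) {
  const double d = xi - center;
  if (kind == 0) return k * d;
  const double ad = std::fabs(d);
  const double s = (d >= 0.0) ? 1.0 : -1.0;
  if (kind == 1) return (ad <= r) ? 0.0 : k * (ad - r) * s;
  return (ad >= r) ? 0.0 : k * (ad - r) * s;
}

static inline double total_bias_grad(const NumericMatrix& biases, double xi) {
  double g = 0.0;
  for (int j = 0; j < biases.nrow(); ++j)
    g += bias_grad((int)biases(j, 0), biases(j, 1), biases(j, 2), biases(j, 3), xi);
  return g;
}

// Overdamped (Brownian) Euler-Maruyama integration on the 1D landscape.
// noise holds pre-drawn standard-normal deviates, one per step, so that the
// trajectory is a deterministic function of (config, noise).
// [[Rcpp::export]]
NumericVector cpp_overdamped(NumericVector amp, NumericVector cen, NumericVector wid,
                             NumericMatrix biases, double xi0, double dt,
                             double gamma, double kT, NumericVector noise,
                             double bound) {
  const int n = noise.size();
  NumericVector traj(n + 1);
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * kT * dt / gamma);
  double xi = xi0;
  traj[0] = xi;
  for (int i = 0; i < n; ++i) {
    const double grad = pot_grad(amp, cen, wid, xi) + total_bias_grad(biases, xi);
    xi += -mob * grad + sig * noise[i];
    if (!std::isfinite(xi) || std::fabs(xi) > bound)
      stop("trajectory diverged at step %d (xi = %g, bound = %g); reduce the "
           "timestep or raise the friction", i + 1, xi, bound);
    traj[i + 1] = xi;
  }
  return traj;
}

// Steered pull: as cpp_overdamped, plus a harmonic restraint whose center moves
// along `centers` (length n_steps + 1; centers[i] applies during step i).
// [[Rcpp::export]]
NumericVector cpp_pull(NumericVector amp, NumericVector cen, NumericVector wid,
                       NumericMatrix biases, NumericVector centers, double k_pull,
                       double xi0, double dt, double gamma, double kT,
                       NumericVector noise, double bound) {
  const int n = noise.size();
  if (centers.size() != n + 1)
    stop("pull schedule must have n_steps + 1 centers (got %d for %d steps)",
         (int)centers.size(), n);
  NumericVector traj(n + 1);
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * kT * dt / gamma);
  double xi = xi0;
  traj[0] = xi;
  for (int i = 0; i < n; ++i) {
    double grad = pot_grad(amp, cen, wid, xi) + total_bias_grad(biases, xi);
    grad += k_pull * (xi - centers[i]);
    xi += -mob * grad + sig * noise[i];
    if (!std::isfinite(xi) || std::fabs(xi) > bound)
      stop("trajectory diverged at step %d (xi = %g, bound = %g); reduce the "
           "timestep or raise the friction", i + 1, xi, bound);
    traj[i + 1] = xi;
  }
  return traj;
}
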