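#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integrator on the synthetic
// landscape plus an optional harmonic bias, with reflecting boundaries.
// Uses R's RNG so trajectories are reproducible under set.seed().
//
//   dr = (D/kT) * F(r) * dt + sqrt(2 D dt) * dW,  F = -dU/dr
//   U(r) = -depth*exp(-(r-wc)^2/(2 w^2)) + exp((r-wp)/ws)
//          + 0.5*spring*(r-center)^2

static inline double force(double r, double depth, double wc, double w2,
                           double wp, double ws, double spring,
                           double center) {
  // -dG/dr of the Gaussian well term
  double f = -depth * std::exp(-(r - wc) * (r - wc) / (2.0 * w2)) *
             (r - wc) / w2;
  // -d/dr of the exponential wall
  f -= std::exp((r - wp) / ws) / ws;
  f -= spring * (r - center);
  return f;
}

// [[Rcpp::export(name = ".langevin_sample_cpp")]]
NumericVector langevin_sample_cpp(double r0, int n_steps, int stride,
                                  int equil_steps, double dt, double diff,
                                  double kT, double domain_min,
                                  double domain_max, double well_depth,
                                  double well_center, double well_width,
                                  double wall_position, double wall_scale,
                                  double spring, double center) {
  if (n_steps < 1 || stride < 1 || equil_steps < 0)
    stop("invalid step counts");
  if (!(domain_min < domain_max))
    stop("domain_min must be < domain_max");

  const double w2 = well_width * well_width;
  const double mob = diff / kT;          // mobility, nm^2 ps^-1 / (kJ/mol)
  const double amp = std::sqrt(2.0 * diff * dt);
  const int n_store = n_steps / stride;
  NumericVector out(n_store);

  RNGScope scope;
  double r = r0;
  if (r < domain_min) r = domain_min;
  if (r > domain_max) r = domain_max;

  for (int i = 0; i < equil_steps; ++i) {
    r += mob * dt * force(r, well_depth, well_center, w2, wall_position,
                          wall_scale, spring, center) +
         amp * norm_rand();
    while (r < domain_min || r > domain_max) {
      if (r < domain_min) r = 2.0 * domain_min - r;
      if (r > domain_max) r = 2.0 * domain_max - r;
    }
  }

  int k = 0;
  for (int i = 1; i <= n_steps; ++i) {
    r += mob * dt * force(r, well_depth, well_center, w2, wall_position,
                          wall_scale, spring, center) +
         amp * norm_rand();
    while (r < domain_min || r > domain_max) {
      if (r < domain_min) r = 2.0 * domain_min - r;
      if (r > domain_max) r = 2.0 * domain_max - r;
    }
    if (i % stride == 0 && k < n_store) out[k++] = r;
  }
  return out;
}
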