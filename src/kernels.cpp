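#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-negative-Gaussian-wells potential, V in kT units.
// grad_out must have length 2; returns energy and fills gradient.
static double wells_energy_grad(const NumericMatrix &centers,
                                const NumericVector &depths,
                                const NumericVector &widths,
                                double x, double y, double *grad_out) {
  double e = 0.0, gx = 0.0, gy = 0.0;
  const int K = centers.nrow();
  for (int k = 0; k < K; ++k) {
    const double dx = x - centers(k, 0);
    const double dy = y - centers(k, 1);
    const double w2 = widths[k] * widths[k];
    const double g = std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
    e += -depths[k] * g;
    // dV/dx = depth * g * dx / w2  (derivative of -depth*exp(...))
    const double f = depths[k] * g / w2;
    gx += f * dx;
    gy += f * dy;
  }
  grad_out[0] = gx;
  grad_out[1] = gy;
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix centers, NumericVector depths,
                         NumericVector widths, NumericMatrix xy) {
  const int n = xy.nrow();
  NumericVector out(n);
  double g[2];
  for (int i = 0; i < n; ++i)
    out[i] = wells_energy_grad(centers, depths, widths, xy(i, 0), xy(i, 1), g);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_force(NumericMatrix centers, NumericVector depths,
                        NumericVector widths, NumericMatrix xy) {
  const int n = xy.nrow();
  NumericMatrix out(n, 2);
  double g[2];
  for (int i = 0; i < n; ++i) {
    wells_energy_grad(centers, depths, widths, xy(i, 0), xy(i, 1), g);
    out(i, 0) = -g[0];
    out(i, 1) = -g[1];
  }
  return out;
}

// Euler-Maruyama overdamped Langevin, fixed number of steps.
// x <- x - grad(V) * dt + sqrt(2 D dt) * xi; unit mobility, so D plays the
// role of kT (Einstein relation) and the stationary density is
// exp(-V / D).  D = 0 is deterministic gradient descent.
// Returns (n_steps + 1) x 2 matrix including the initial point.
// [[Rcpp::export]]
NumericMatrix cpp_propagate(NumericMatrix centers, NumericVector depths,
                            NumericVector widths, NumericVector x0,
                            double dt, double D, int n_steps) {
  RNGScope scope;
  NumericMatrix out(n_steps + 1, 2);
  double x = x0[0], y = x0[1], g[2];
  const double noise = std::sqrt(2.0 * D * dt);
  out(0, 0) = x;
  out(0, 1) = y;
  for (int s = 1; s <= n_steps; ++s) {
    wells_energy_grad(centers, depths, widths, x, y, g);
    x += -g[0] * dt + noise * norm_rand();
    y += -g[1] * dt + noise * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("non-finite coordinate at step %d: timestep too large for this potential", s);
    out(s, 0) = x;
    out(s, 1) = y;
  }
  return out;
}

static int disc_state(const NumericMatrix &scenters, const NumericVector &sradii,
                      double x, double y) {
  const int S = scenters.nrow();
  for (int s = 0; s < S; ++s) {
    const double dx = x - scenters(s, 0);
    const double dy = y - scenters(s, 1);
    if (dx * dx + dy * dy <= sradii[s] * sradii[s]) return s + 1; // 1-based
  }
  return 0;
}

// Generate a shooting segment: new frames only (excluding x0), stopping as
// soon as a newly generated frame lies inside any state disc, or after
// max_steps frames.  Returns list(coords, state) with state = 0 if the
// segment hit max_steps without reaching a state.
// [[Rcpp::export]]
List cpp_shoot_segment(NumericMatrix centers, NumericVector depths,
                       NumericVector widths, NumericMatrix scenters,
                       NumericVector sradii, NumericVector x0,
                       double dt, double D, int max_steps) {
  RNGScope scope;
  NumericMatrix buf(max_steps, 2);
  double x = x0[0], y = x0[1], g[2];
  const double noise = std::sqrt(2.0 * D * dt);
  int n = 0, state = 0;
  while (n < max_steps) {
    wells_energy_grad(centers, depths, widths, x, y, g);
    x += -g[0] * dt + noise * norm_rand();
    y += -g[1] * dt + noise * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("non-finite coordinate in shooting segment: timestep too large");
    buf(n, 0) = x;
    buf(n, 1) = y;
    ++n;
    state = disc_state(scenters, sradii, x, y);
    if (state > 0) break;
  }
  NumericMatrix coords(n, 2);
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = buf(i, 0);
    coords(i, 1) = buf(i, 1);
  }
  return List::create(_["coords"] = coords, _["state"] = state);
}

// Discrete-time Markov chain over 1..m given a row-stochastic matrix P
// (diagonal included).  Returns n 1-based labels starting from `start`.
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(NumericMatrix P, int start, int n) {
  RNGScope scope;
  const int m = P.nrow();
  IntegerVector out(n);
  int cur = start - 1;
  for (int t = 0; t < n; ++t) {
    out[t] = cur + 1;
    if (t == n - 1) break;
    const double u = unif_rand();
    double acc = 0.0;
    int nxt = m - 1; // guard against rounding
    for (int j = 0; j < m; ++j) {
      acc += P(cur, j);
      if (u < acc) { nxt = j; break; }
    }
    cur = nxt;
  }
  return out;
}
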