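#include <Rcpp.h>
using namespace Rcpp;

// Lattice random walk exit-time sampler.
//
// Positions are integers (lattice units of dx).  A walk starts at x0_idx and
// each step moves +1 with probability p_by_step[k] (recycled at its last
// value beyond its length) or -1 otherwise.  Absorption at <= 0 (growth) or,
// when L_idx > 0, at >= L_idx (death); otherwise censoring at max_steps.
// Uses R's RNG stream so set.seed() governs reproducibility.
//
// [[Rcpp::export]]
List cpp_sample_exit_steps(int n, int x0_idx, int L_idx,
                           NumericVector p_by_step, int max_steps) {
  if (n < 0) stop("n must be non-negative");
  if (x0_idx <= 0) stop("x0 must lie strictly above the growth threshold");
  if (L_idx > 0 && x0_idx >= L_idx) stop("x0 must lie strictly below L");
  const int n_p = p_by_step.size();
  if (n_p < 1) stop("p_by_step must have at least one element");
  for (int k = 0; k < n_p; ++k) {
    if (p_by_step[k] < 0.0 || p_by_step[k] > 1.0 || NumericVector::is_na(p_by_step[k]))
      stop("step-up probabilities must lie in [0, 1]");
  }
  IntegerVector steps(n);
  IntegerVector side(n);  // 0 = growth, 1 = death, 2 = censored
  for (int i = 0; i < n; ++i) {
    int pos = x0_idx;
    int k = 0;
    int s = 2;
    while (k < max_steps) {
      const double p = p_by_step[k < n_p ? k : n_p - 1];
      pos += (unif_rand() < p) ? 1 : -1;
      ++k;
      if (pos <= 0) { s = 0; break; }
      if (L_idx > 0 && pos >= L_idx) { s = 1; break; }
    }
    steps[i] = k;
    side[i] = s;
  }
  return List::create(_["steps"] = steps, _["side"] = side);
}

// Deterministic occupancy propagation: exact marginal law of the lattice
// walk.  Interior sites are 1..K-1.  Returns the survival curve S(k), the
// cumulative absorbed mass at each boundary after each step, and the final
// interior occupancy.
//
// [[Rcpp::export]]
List cpp_propagate_occupancy(NumericVector mass, double absorbed_growth,
                             double absorbed_death, NumericVector p_by_step,
                             int steps) {
  const int m = mass.size();     // interior sites 1..K-1, K = m + 1
  if (m < 1) stop("occupancy grid needs at least one interior site");
  const int n_p = p_by_step.size();
  if (n_p < 1) stop("p_by_step must have at least one element");
  for (int k = 0; k < n_p; ++k) {
    if (p_by_step[k] < 0.0 || p_by_step[k] > 1.0 || NumericVector::is_na(p_by_step[k]))
      stop("step-up probabilities must lie in [0, 1]");
  }
  std::vector<double> cur(mass.begin(), mass.end());
  std::vector<double> nxt(m, 0.0);
  NumericVector surv(steps + 1), abs_g(steps + 1), abs_d(steps + 1);
  double ag = absorbed_growth, ad = absorbed_death;
  double interior = 0.0;
  for (int j = 0; j < m; ++j) interior += cur[j];
  surv[0] = interior; abs_g[0] = ag; abs_d[0] = ad;
  for (int k = 0; k < steps; ++k) {
    const double p = p_by_step[k < n_p ? k : n_p - 1];
    const double q = 1.0 - p;
    for (int j = 0; j < m; ++j) nxt[j] = 0.0;
    // site j (0-based; lattice site j+1) sends p up, q down
    ag += q * cur[0];
    ad += p * cur[m - 1];
    for (int j = 0; j < m - 1; ++j) nxt[j + 1] += p * cur[j];
    for (int j = 1; j < m; ++j)     nxt[j - 1] += q * cur[j];
    cur.swap(nxt);
    interior = 0.0;
    for (int j = 0; j < m; ++j) interior += cur[j];
    surv[k + 1] = interior; abs_g[k + 1] = ag; abs_d[k + 1] = ad;
  }
  return List::create(_["survival"] = surv,
                      _["absorbed_growth"] = abs_g,
                      _["absorbed_death"] = abs_d,
                      _["mass"] = NumericVector(cur.begin(), cur.end()));
}

// Occupancy-propagated survival curves for many subjects at once.  Subject i
// has step-up probability p_{i,k} = 1/2 - mult[i] * vbar_by_step[k] * dt /
// (2 dx) at step k.  All subjects share the lattice (K sites, start x0_idx).
// Returns an n x (steps + 1) matrix of interior (survival) mass.
//
// [[Rcpp::export]]
NumericMatrix cpp_occupancy_survival_multi(int K, int x0_idx,
                                           NumericVector vbar_by_step,
                                           NumericVector mult,
                                           double dt, double dx, int steps) {
  const int n = mult.size();
  const int m = K - 1;
  if (m < 1) stop("lattice needs at least one interior site");
  if (x0_idx <= 0 || x0_idx >= K) stop("x0 must lie strictly inside (0, L)");
  const int n_v = vbar_by_step.size();
  if (n_v < 1) stop("vbar_by_step must have at least one element");
  NumericMatrix surv(n, steps + 1);
  std::vector<double> cur((size_t)n * m, 0.0), nxt((size_t)n * m, 0.0);
  for (int i = 0; i < n; ++i) cur[(size_t)i * m + (x0_idx - 1)] = 1.0;
  for (int i = 0; i < n; ++i) surv(i, 0) = 1.0;
  std::vector<double> p(n);
  for (int k = 0; k < steps; ++k) {
    const double vbar = vbar_by_step[k < n_v ? k : n_v - 1];
    for (int i = 0; i < n; ++i) {
      p[i] = 0.5 - mult[i] * vbar * dt / (2.0 * dx);
      if (p[i] < 0.0 || p[i] > 1.0)
        stop("drift too large for the lattice: step-up probability outside [0, 1]");
    }
    for (int i = 0; i < n; ++i) {
      double *c = &cur[(size_t)i * m];
      double *x = &nxt[(size_t)i * m];
      const double pi = p[i], qi = 1.0 - pi;
      if (m == 1) {
        x[0] = 0.0;  // single interior site: all mass absorbed each step
      } else {
        x[0] = qi * c[1];
        for (int j = 1; j < m - 1; ++j) x[j] = pi * c[j - 1] + qi * c[j + 1];
        x[m - 1] = pi * c[m - 2];
      }
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += x[j];
      surv(i, k + 1) = s;
    }
    cur.swap(nxt);
  }
  return surv;
}
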