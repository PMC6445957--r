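#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>

// Integer-encoded reaction network (see model_compile() on the R side).
// law: 0 = hill_activation, 1 = hill_repression, 2 = mass_action.
struct Reaction {
  int law;
  std::vector<int> pidx;      // hill: vmax,a,m0,h   mass action: k
  std::vector<int> mod_idx;   // hill: species summed into the modifier
  std::vector<int> pidx2;     // optional second activator: a2,m02
  std::vector<int> mod2_idx;
  std::vector<int> rate_idx;  // mass action: species whose product is the rate
  std::vector<int> st_idx;
  std::vector<double> st_coef;
};

struct Model {
  int n_species;
  int n_params;
  std::vector<Reaction> rx;
  std::vector<int> env_idx;
  std::vector<int> rule_idx;
  // environment slots are exchange accumulators owned by the lattice; they
  // are clipped like ordinary species but do not drive the sub-step control
  std::vector<char> is_env;
};

inline Model parse_model(const Rcpp::List& compiled) {
  Model M;
  M.n_species = Rcpp::as<int>(compiled["n_species"]);
  M.n_params  = Rcpp::as<int>(compiled["n_params"]);
  Rcpp::List rxs = compiled["reactions"];
  for (int i = 0; i < rxs.size(); ++i) {
    Rcpp::List r = rxs[i];
    Reaction q;
    q.law = Rcpp::as<int>(r["law"]);
    q.pidx = Rcpp::as<std::vector<int>>(r["pidx"]);
    q.st_idx = Rcpp::as<std::vector<int>>(r["stoich_idx"]);
    q.st_coef = Rcpp::as<std::vector<double>>(r["stoich_coef"]);
    if (q.law == 2) {
      q.rate_idx = Rcpp::as<std::vector<int>>(r["rate_idx"]);
    } else {
      q.mod_idx = Rcpp::as<std::vector<int>>(r["mod_idx"]);
      q.pidx2 = Rcpp::as<std::vector<int>>(r["pidx2"]);
      q.mod2_idx = Rcpp::as<std::vector<int>>(r["mod2_idx"]);
    }
    M.rx.push_back(q);
  }
  M.env_idx = Rcpp::as<std::vector<int>>(compiled["env_idx"]);
  M.rule_idx = Rcpp::as<std::vector<int>>(compiled["rule_idx"]);
  M.is_env.assign(M.n_species, 0);
  for (int e : M.env_idx) M.is_env[e] = 1;
  return M;
}

inline double powh(double x, double h) {
  return (h == 2.0) ? x * x : std::pow(x, h);
}

// Saturating activation factor in [1/a, 1].
inline double hill_factor_act(double mod, double a, double m0, double h) {
  double mh = powh(mod, h), m0h = powh(m0, h);
  return 1.0 / a + (1.0 - 1.0 / a) * mh / (mh + m0h);
}
inline double hill_factor_rep(double mod, double a, double m0, double h) {
  double mh = powh(mod, h), m0h = powh(m0, h);
  return 1.0 / a + (1.0 - 1.0 / a) * m0h / (mh + m0h);
}

// Per-reaction rates at state x with parameter vector p.
inline void reaction_rates_cpp(const Model& M, const double* x, const double* p,
                               double* rate) {
  for (size_t j = 0; j < M.rx.size(); ++j) {
    const Reaction& q = M.rx[j];
    double v;
    if (q.law == 2) {
      v = p[q.pidx[0]];
      for (int s : q.rate_idx) v *= x[s];
    } else {
      double mod = 0.0;
      for (int s : q.mod_idx) mod += x[s];
      double vmax = p[q.pidx[0]], a = p[q.pidx[1]], m0 = p[q.pidx[2]],
             h = p[q.pidx[3]];
      v = (q.law == 0) ? vmax * hill_factor_act(mod, a, m0, h)
                       : vmax * hill_factor_rep(mod, a, m0, h);
      if (!q.pidx2.empty()) {
        double mod2 = 0.0;
        for (int s : q.mod2_idx) mod2 += x[s];
        v *= hill_factor_act(mod2, p[q.pidx2[0]], p[q.pidx2[1]], h);
      }
    }
    rate[j] = v;
  }
}

// One clipped forward-Euler micro-step of size hstep. Reaction fluxes are
// scaled down so no species is consumed below zero within the step; scaling a
// whole reaction (not single stoichiometric entries) preserves its mass
// balance. Returns the largest |dx|/max(x, floor) observed (for the
// sub-stepping criterion) without committing the update; the proposed dx is
// left in dx[].
inline double propose_euler(const Model& M, const double* x, const double* p,
                            double hstep, double* rate, double* cons,
                            double* dx) {
  reaction_rates_cpp(M, x, p, rate);
  const int n = M.n_species;
  for (int i = 0; i < n; ++i) { cons[i] = 0.0; dx[i] = 0.0; }
  for (size_t j = 0; j < M.rx.size(); ++j) {
    const Reaction& q = M.rx[j];
    for (size_t k = 0; k < q.st_idx.size(); ++k)
      if (q.st_coef[k] < 0) cons[q.st_idx[k]] -= q.st_coef[k] * rate[j];
  }
  for (size_t j = 0; j < M.rx.size(); ++j) {
    const Reaction& q = M.rx[j];
    double f = 1.0;
    for (size_t k = 0; k < q.st_idx.size(); ++k) {
      if (q.st_coef[k] < 0) {
        int i = q.st_idx[k];
        double need = cons[i] * hstep;
        if (need > x[i] && need > 0.0) {
          double fi = x[i] / need;
          if (fi < f) f = fi;
        }
      }
    }
    double w = rate[j] * hstep * f;
    for (size_t k = 0; k < q.st_idx.size(); ++k)
      dx[q.st_idx[k]] += q.st_coef[k] * w;
  }
  const double floor_amt = 1.0;
  double worst = 0.0;
  for (int i = 0; i < n; ++i) {
    if (M.is_env[i]) continue;
    double rel = std::fabs(dx[i]) / std::max(x[i], floor_amt);
    if (rel > worst) worst = rel;
  }
  return worst;
}

// Advance one cell state over dt with adaptive halving: the step is split
// whenever any variable would change by more than 25% within one micro-step.
inline void cell_step_cpp(const Model& M, double* x, const double* p,
                          double dt, int max_halvings,
                          double* rate, double* cons, double* dx) {
  const int n = M.n_species;
  double remaining = dt;
  double hstep = dt;
  double hmin = dt / std::pow(2.0, max_halvings);
  while (remaining > 1e-12) {
    if (hstep > remaining) hstep = remaining;
    double worst = propose_euler(M, x, p, hstep, rate, cons, dx);
    if (worst > 0.25 && hstep > hmin) {
      hstep *= 0.5;
      continue;
    }
    for (int i = 0; i < n; ++i) {
      x[i] += dx[i];
      if (x[i] < 0.0) x[i] = 0.0;  // guards round-off only; clipping is exact
      if (!std::isfinite(x[i]))
        Rcpp::stop("non-finite state in species index %d", i + 1);
    }
    remaining -= hstep;
    if (worst < 0.1 && hstep < remaining) hstep *= 2.0;
  }
}
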