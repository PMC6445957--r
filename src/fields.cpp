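#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit 5-point-stencil diffusion with Dirichlet boundaries: the outermost
// lattice ring is held at `boundary` throughout. lambda = D*dt/dx^2 is split
// into sub-steps so each sub-step satisfies lambda <= 0.25.
void diffuse_inplace(NumericMatrix f, double D, double dt, double dx,
                     double boundary, int max_substeps) {
  if (D <= 0 || dt <= 0) return;
  const int nr = f.nrow(), nc = f.ncol();
  double lambda = D * dt / (dx * dx);
  int m = (int)std::ceil(lambda / 0.25);
  if (m < 1) m = 1;
  if (m > max_substeps)
    stop("diffusion unstable: lambda=%.3g needs %d sub-steps (max %d)",
         lambda, m, max_substeps);
  double lam = lambda / m;
  for (int j = 0; j < nc; ++j) { f(0, j) = boundary; f(nr - 1, j) = boundary; }
  for (int i = 0; i < nr; ++i) { f(i, 0) = boundary; f(i, nc - 1) = boundary; }
  NumericMatrix g(nr, nc);
  for (int s = 0; s < m; ++s) {
    for (int j = 1; j < nc - 1; ++j)
      for (int i = 1; i < nr - 1; ++i)
        g(i, j) = f(i, j) + lam * (f(i - 1, j) + f(i + 1, j) + f(i, j - 1) +
                                   f(i, j + 1) - 4.0 * f(i, j));
    for (int j = 1; j < nc - 1; ++j)
      for (int i = 1; i < nr - 1; ++i)
        f(i, j) = g(i, j);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, double D, double dt, double dx,
                          double boundary, int max_substeps) {
  NumericMatrix f = clone(field);
  diffuse_inplace(f, D, dt, dx, boundary, max_substeps);
  return f;
}

void degrade_inplace(NumericMatrix f, double k, double dt) {
  if (k <= 0 || dt <= 0) return;
  double fac = 1.0 - k * dt;
  if (fac < 0) fac = 0;
  for (int j = 0; j < f.ncol(); ++j)
    for (int i = 0; i < f.nrow(); ++i)
      f(i, j) *= fac;
}

// [[Rcpp::export]]
NumericMatrix cpp_degrade(NumericMatrix field, double k, double dt) {
  NumericMatrix f = clone(field);
  degrade_inplace(f, k, dt);
  return f;
}

// Medium replenishment: sitewise influx k_in*(reference - local)*dt. The law
// is signed, so sites above the reference lose molecules to the medium.
void replenish_inplace(NumericMatrix f, double reference, double k_in,
                       double dt) {
  if (k_in <= 0 || dt <= 0) return;
  double w = k_in * dt;
  if (w > 1) w = 1;   // cannot overshoot the reference within one step
  for (int j = 0; j < f.ncol(); ++j)
    for (int i = 0; i < f.nrow(); ++i)
      f(i, j) += w * (reference - f(i, j));
}

// [[Rcpp::export]]
NumericMatrix cpp_replenish(NumericMatrix field, double reference, double k_in,
                            double dt) {
  NumericMatrix f = clone(field);
  replenish_inplace(f, reference, k_in, dt);
  return f;
}

// Sitewise mass-action binding of extracellular sVEGFR1 to VEGF-A forming the
// inert complex sVEGFR1b. Conservative: every particle leaving vegf/sv enters
// svb and vice versa; fluxes are clipped so no site goes negative.
void svegfr1_kinetics_inplace(NumericMatrix vegf, NumericMatrix sv,
                              NumericMatrix svb, double k_on, double k_off,
                              double dt) {
  if (dt <= 0) return;
  for (int j = 0; j < vegf.ncol(); ++j)
    for (int i = 0; i < vegf.nrow(); ++i) {
      double d = (k_on * vegf(i, j) * sv(i, j) - k_off * svb(i, j)) * dt;
      if (d > 0) {
        if (d > vegf(i, j)) d = vegf(i, j);
        if (d > sv(i, j)) d = sv(i, j);
      } else if (-d > svb(i, j)) {
        d = -svb(i, j);
      }
      vegf(i, j) -= d;
      sv(i, j) -= d;
      svb(i, j) += d;
    }
}

// [[Rcpp::export]]
List cpp_svegfr1_kinetics(NumericMatrix vegf, NumericMatrix sv,
                          NumericMatrix svb, double k_on, double k_off,
                          double dt) {
  NumericMatrix v = clone(vegf), s = clone(sv), b = clone(svb);
  svegfr1_kinetics_inplace(v, s, b, k_on, k_off, dt);
  return List::create(_["vegf"] = v, _["svegfr1"] = s, _["svegfr1b"] = b);
}
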