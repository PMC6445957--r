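#include "model.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_reaction_rates(List compiled, NumericVector state,
                                 NumericVector params) {
  Model M = parse_model(compiled);
  if ((int)state.size() != M.n_species) stop("state length mismatch");
  if ((int)params.size() != M.n_params) stop("params length mismatch");
  NumericVector out(M.rx.size());
  reaction_rates_cpp(M, state.begin(), params.begin(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cell_step(List compiled, NumericVector state,
                            NumericVector params, double dt,
                            int max_halvings) {
  Model M = parse_model(compiled);
  if ((int)state.size() != M.n_species) stop("state length mismatch");
  if ((int)params.size() != M.n_params) stop("params length mismatch");
  NumericVector x = clone(state);
  std::vector<double> rate(M.rx.size()), cons(M.n_species), dx(M.n_species);
  if (dt < 0) stop("dt must be >= 0");
  if (dt > 0)
    cell_step_cpp(M, x.begin(), params.begin(), dt, max_halvings,
                  rate.data(), cons.data(), dx.data());
  return x;
}

// Static lattice of coupled cells (no movement, no fields): used for the
// two-cell and 1-D ring lateral-inhibition fixtures. Cells exchange Dll4
// through the sharing rule (each neighbor's surface ligand divided by that
// neighbor's own contact count) and sit in a VEGF bath clamped at vegf_bath.
// Cells are updated sequentially (fixed order) and asynchronously: trans
// binding consumes the presenting neighbor's Dll4 immediately.
//
// neighbors: 0-based adjacency list; vegf/dll4/sv/svb env slot indices are
// taken from the compiled model's env ordering (vegf, sv, svb, dll4_nb).
// [[Rcpp::export]]
List cpp_simulate_static(List compiled, NumericMatrix states,
                         NumericMatrix params, List neighbors,
                         double vegf_bath, double dt, int n_steps,
                         int record_every, int max_halvings) {
  Model M = parse_model(compiled);
  const int ncell = states.nrow();
  if (states.ncol() != M.n_species) stop("state matrix column mismatch");
  if (params.nrow() != ncell) stop("one parameter row per cell required");
  if (M.env_idx.size() != 4) stop("model must declare 4 environment slots");
  const int iv = M.env_idx[0], isv = M.env_idx[1], isvb = M.env_idx[2],
            idn = M.env_idx[3];

  std::vector<std::vector<int>> nb(ncell);
  for (int i = 0; i < ncell; ++i)
    nb[i] = as<std::vector<int>>(neighbors[i]);

  // which species is dll4? the ligand consumed on the presenting cell: the
  // compiled list carries species names
  CharacterVector spn = compiled["species"];
  int idll4 = -1;
  for (int i = 0; i < spn.size(); ++i)
    if (spn[i] == "dll4") idll4 = i;
  if (idll4 < 0) stop("model must contain a 'dll4' species");

  NumericMatrix X = clone(states);
  std::vector<double> rate(M.rx.size()), cons(M.n_species), dx(M.n_species);
  std::vector<double> xi(M.n_species), pi(M.n_params);

  int nrec = n_steps / record_every + 1;
  // trajectories: one matrix per cell, rows = record points
  List traj(ncell);
  std::vector<NumericMatrix> tr;
  for (int i = 0; i < ncell; ++i) tr.push_back(NumericMatrix(nrec, M.n_species));
  NumericVector tvec(nrec);
  int rrow = 0;
  for (int i = 0; i < ncell; ++i)
    for (int s = 0; s < M.n_species; ++s) tr[i](0, s) = X(i, s);
  tvec[0] = 0.0;
  rrow = 1;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < ncell; ++i) {
      // gather neighbor Dll4 with per-contact sharing
      double dnb = 0.0;
      std::vector<double> share(nb[i].size());
      for (size_t k = 0; k < nb[i].size(); ++k) {
        int j = nb[i][k];
        double s = X(j, idll4) / std::max((size_t)1, nb[j].size());
        share[k] = s;
        dnb += s;
      }
      for (int s = 0; s < M.n_species; ++s) xi[s] = X(i, s);
      xi[iv] = vegf_bath;   // clamped bath, not depleted
      xi[isv] = 0.0; xi[isvb] = 0.0;
      xi[idn] = dnb;
      for (int q = 0; q < M.n_params; ++q) pi[q] = params(i, q);
      cell_step_cpp(M, xi.data(), pi.data(), dt, max_halvings,
                    rate.data(), cons.data(), dx.data());
      // scatter Dll4 consumption back onto the presenting neighbors
      double used = dnb - xi[idn];
      if (used > 0 && dnb > 0) {
        double f = used / dnb;
        for (size_t k = 0; k < nb[i].size(); ++k)
          X(nb[i][k], idll4) -= share[k] * f;
      }
      xi[iv] = 0.0; xi[isv] = 0.0; xi[isvb] = 0.0; xi[idn] = 0.0;
      for (int s = 0; s < M.n_species; ++s) X(i, s) = xi[s];
    }
    if (step % record_every == 0 && rrow < nrec) {
      for (int i = 0; i < ncell; ++i)
        for (int s = 0; s < M.n_species; ++s) tr[i](rrow, s) = X(i, s);
      tvec[rrow] = step * dt;
      ++rrow;
    }
  }
  for (int i = 0; i < ncell; ++i) traj[i] = tr[i];
  return List::create(_["time"] = tvec, _["traj"] = traj,
                      _["final"] = X);
}
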