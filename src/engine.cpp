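#include "model.h"
#include <chrono>
using namespace Rcpp;

namespace {
inline double now_s() {
  return std::chrono::duration<double>(
             std::chrono::steady_clock::now().time_since_epoch())
      .count();
}
}

void diffuse_inplace(NumericMatrix f, double D, double dt, double dx,
                     double boundary, int max_substeps);
void degrade_inplace(NumericMatrix f, double k, double dt);
void replenish_inplace(NumericMatrix f, double reference, double k_in,
                       double dt);
void svegfr1_kinetics_inplace(NumericMatrix vegf, NumericMatrix sv,
                              NumericMatrix svb, double k_on, double k_off,
                              double dt);

namespace {

// compass order: clockwise from north; deviations of +-45 degrees are +-1
const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

struct Agent {
  int id;
  int r, c;
  bool tip;
  std::vector<double> x;  // full state vector (n_species)
  std::vector<double> p;  // per-cell parameter vector
};

struct Behavior {
  double A_star, D_star, filo_ext, filo_ret, v2a_set, filo_max;
  double p_dev, move_rate;
};

int ifloor(double v) { return (int)std::floor(v); }

// Directional-derivative score of the VEGF field along each of the 8 lattice
// directions: mean slope (value difference from the cell's site per unit
// distance) over the sensing radius. Returns -1 when locally uniform; ties
// between equal maxima are broken uniformly at random.
int gradient_direction_core(const Rcpp::NumericMatrix& vegf, int r, int c,
                            int radius) {
  const int nr = vegf.nrow(), nc = vegf.ncol();
  const double SQ2 = std::sqrt(2.0);
  double here = vegf(r, c);
  double score[8];
  bool any_diff = false;
  for (int d = 0; d < 8; ++d) {
    double len = (DR[d] != 0 && DC[d] != 0) ? SQ2 : 1.0;
    double s = 0.0;
    int used = 0;
    for (int k = 1; k <= radius; ++k) {
      int rr = r + k * DR[d], cc = c + k * DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) break;
      s += (vegf(rr, cc) - here) / (k * len);
      ++used;
    }
    score[d] = (used > 0) ? s / used : -HUGE_VAL;
    if (used > 0 && std::fabs(s) > 1e-12 * (1.0 + std::fabs(here)))
      any_diff = true;
  }
  if (!any_diff) return -1;
  double best = score[0];
  for (int d = 1; d < 8; ++d) if (score[d] > best) best = score[d];
  int ties[8], nt = 0;
  for (int d = 0; d < 8; ++d)
    if (score[d] >= best - 1e-12 * (1.0 + std::fabs(best))) ties[nt++] = d;
  return ties[(int)(unif_rand() * nt) % nt];
}

// moment-matched log-normal: distribution mean mu, standard deviation sd
std::vector<double> sample_params(const std::vector<double>& mu,
                                  const std::vector<double>& sd) {
  std::vector<double> out(mu.size());
  for (size_t i = 0; i < mu.size(); ++i) {
    if (sd[i] <= 0.0 || mu[i] <= 0.0) {
      out[i] = mu[i];
    } else {
      double s2 = std::log(1.0 + (sd[i] * sd[i]) / (mu[i] * mu[i]));
      double meanlog = std::log(mu[i]) - 0.5 * s2;
      out[i] = std::exp(meanlog + std::sqrt(s2) * norm_rand());
    }
  }
  return out;
}

int find_species(const CharacterVector& spn, const char* name) {
  for (int i = 0; i < spn.size(); ++i)
    if (spn[i] == name) return i;
  stop("packaged model is missing species '%s'", name);
  return -1;
}

}  // namespace

// Full simulation run. All stochasticity draws from R's RNG so runs are
// reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List cpp_run(List compiled, List cfg) {
  Model M = parse_model(compiled);
  CharacterVector spn = compiled["species"];
  if (M.env_idx.size() != 4) stop("model must declare 4 environment slots");
  const int iv = M.env_idx[0], isv = M.env_idx[1], isvb = M.env_idx[2],
            idn = M.env_idx[3];
  const int i_dll4 = find_species(spn, "dll4");
  const int i_r1m = find_species(spn, "vegfr1_mRNA");
  const int i_r2m = find_species(spn, "vegfr2_mRNA");
  const int i_d4m = find_species(spn, "dll4_mRNA");
  const int i_v2a = find_species(spn, "vegfr2_active");
  const int i_filo = find_species(spn, "filopodia");

  const int nr = as<int>(cfg["nr"]), nc = as<int>(cfg["nc"]);
  const double dt = as<double>(cfg["dt"]);
  const double t_end = as<double>(cfg["t_end"]);
  NumericVector out_times = cfg["output_times"];
  const int max_substeps = as<int>(cfg["max_substeps"]);
  const int max_halvings = as<int>(cfg["max_halvings"]);

  const double D_vegf = as<double>(cfg["D_vegf"]),
               D_sv = as<double>(cfg["D_sv"]), D_svb = as<double>(cfg["D_svb"]);
  const double kdeg_vegf = as<double>(cfg["kdeg_vegf"]),
               kdeg_sv = as<double>(cfg["kdeg_sv"]),
               kdeg_svb = as<double>(cfg["kdeg_svb"]);
  const double vegf_ref = as<double>(cfg["vegf_ref"]),
               k_in = as<double>(cfg["k_in"]);
  const double k_on_sv = as<double>(cfg["k_on_sv"]),
               k_off_sv = as<double>(cfg["k_off_sv"]);

  List beh = cfg["behavior"];
  Behavior B;
  B.A_star = as<double>(beh["A_star"]);
  B.D_star = as<double>(beh["D_star"]);
  B.filo_ext = as<double>(beh["filo_ext"]);
  B.filo_ret = as<double>(beh["filo_ret"]);
  B.v2a_set = as<double>(beh["v2a_set"]);
  B.filo_max = as<double>(beh["filo_max"]);
  B.p_dev = as<double>(beh["p_dev"]);
  B.move_rate = as<double>(beh["move_rate"]);

  std::vector<double> mu = as<std::vector<double>>(cfg["param_mu"]);
  std::vector<double> sd = as<std::vector<double>>(cfg["param_sd"]);
  NumericVector x0 = cfg["initial_state"];
  if ((int)x0.size() != M.n_species) stop("initial state length mismatch");
  // per-cell log-normal sampling of initial amounts (same SD/mean ratio as
  // the sampled parameters; zero-mean and environment slots stay fixed)
  std::vector<double> x0mu = as<std::vector<double>>(x0);
  std::vector<double> x0sd = as<std::vector<double>>(cfg["initial_sd"]);

  // fields
  NumericMatrix vegf(nr, nc), sv(nr, nc), svb(nr, nc);
  std::fill(vegf.begin(), vegf.end(), vegf_ref);

  // agents
  IntegerMatrix seeds = cfg["seed_sites"];  // n0 x 2, 0-based (row, col)
  std::vector<Agent> agents;
  IntegerMatrix occ(nr, nc);
  int next_id = 1;
  for (int k = 0; k < seeds.nrow(); ++k) {
    int r = seeds(k, 0), c = seeds(k, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc) stop("seed site outside grid");
    if (occ(r, c)) continue;
    Agent a;
    a.id = next_id++;
    a.r = r; a.c = c; a.tip = false;
    a.x = sample_params(x0mu, x0sd);
    a.p = sample_params(mu, sd);
    agents.push_back(a);
    occ(r, c) = (int)agents.size();
  }

  const int n_steps = (int)std::lround(t_end / dt);
  std::vector<double> ser_t, ser_n, ser_tips;
  ser_t.reserve(n_steps + 1);

  List snapshots;
  std::vector<double> snap_times;
  for (int k = 0; k < out_times.size(); ++k)
    if (out_times[k] <= t_end + 1e-9) snap_times.push_back(out_times[k]);

  std::vector<double> rate(M.rx.size()), cons(M.n_species), dx(M.n_species);
  std::vector<double> xi(M.n_species);
  std::vector<int> perm;

  // count of occupied Moore neighbors of an agent (for Dll4 sharing)
  auto contact_count = [&](int r, int c) {
    int n = 0;
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && occ(rr, cc)) ++n;
    }
    return n;
  };

  auto take_snapshot = [&](double tnow) {
    int n = (int)agents.size();
    IntegerVector id(n), rr(n), cc(n), tip(n);
    NumericMatrix st(n, M.n_species);
    IntegerMatrix om(nr, nc);
    for (int i = 0; i < n; ++i) {
      id[i] = agents[i].id; rr[i] = agents[i].r; cc[i] = agents[i].c;
      tip[i] = agents[i].tip ? 1 : 0;
      om(agents[i].r, agents[i].c) = agents[i].tip ? 2 : 1;
      for (int s = 0; s < M.n_species; ++s) st(i, s) = agents[i].x[s];
    }
    return List::create(_["time"] = tnow, _["occupancy"] = om,
                        _["vegf"] = clone(vegf), _["id"] = id, _["row"] = rr,
                        _["col"] = cc, _["tip"] = tip, _["state"] = st);
  };

  size_t next_snap = 0;
  // snapshot at t = 0 always recorded
  snapshots.push_back(take_snapshot(0.0));
  while (next_snap < snap_times.size() && snap_times[next_snap] <= 1e-9)
    ++next_snap;
  {
    int ntip0 = 0;
    ser_t.push_back(0.0); ser_n.push_back((double)agents.size());
    ser_tips.push_back(ntip0);
  }

  double t_fields = 0, t_cell = 0, t_gather = 0, t_move = 0;
  long n_cellsteps = 0;
  long mv_attempt = 0, mv_blocked = 0, mv_nodonor = 0, mv_ok = 0,
       mv_offgrid = 0;

  for (int step = 1; step <= n_steps; ++step) {
    double tnow = step * dt;

    double tt0 = now_s();
    // ---- fields: diffuse -> react -> degrade -> replenish
    diffuse_inplace(vegf, D_vegf, dt, 1.0, vegf_ref, max_substeps);
    diffuse_inplace(sv, D_sv, dt, 1.0, 0.0, max_substeps);
    diffuse_inplace(svb, D_svb, dt, 1.0, 0.0, max_substeps);
    svegfr1_kinetics_inplace(vegf, sv, svb, k_on_sv, k_off_sv, dt);
    degrade_inplace(vegf, kdeg_vegf, dt);
    degrade_inplace(sv, kdeg_sv, dt);
    degrade_inplace(svb, kdeg_svb, dt);
    replenish_inplace(vegf, vegf_ref, k_in, dt);
    t_fields += now_s() - tt0;

    // ---- agents, fresh random permutation each step
    int n_now = (int)agents.size();
    perm.resize(n_now);
    for (int i = 0; i < n_now; ++i) perm[i] = i;
    for (int i = n_now - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    for (int pi = 0; pi < n_now; ++pi) {
      Agent& a = agents[perm[pi]];
      double tg0 = now_s();

      // gather neighbor Dll4 (shared per contact)
      double dnb = 0.0;
      int nbi[8]; double nbshare[8]; int nnb = 0;
      for (int d = 0; d < 8; ++d) {
        int rr = a.r + DR[d], cc = a.c + DC[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int o = occ(rr, cc);
        if (!o) continue;
        Agent& b = agents[o - 1];
        int cnt = contact_count(rr, cc);
        double s = b.x[i_dll4] / std::max(1, cnt);
        nbi[nnb] = o - 1; nbshare[nnb] = s; ++nnb;
        dnb += s;
      }

      // gather VEGF over the sensing ball (Chebyshev radius 1 + filopodia)
      int R = 1 + ifloor(a.x[i_filo]);
      int r0 = std::max(0, a.r - R), r1 = std::min(nr - 1, a.r + R);
      int c0 = std::max(0, a.c - R), c1 = std::min(nc - 1, a.c + R);
      double vsum = 0.0;
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr) vsum += vegf(rr, cc);

      for (int s = 0; s < M.n_species; ++s) xi[s] = a.x[s];
      xi[iv] = vsum; xi[isv] = 0.0; xi[isvb] = 0.0; xi[idn] = dnb;

      double tc0 = now_s();
      t_gather += tc0 - tg0;
      cell_step_cpp(M, xi.data(), a.p.data(), dt, max_halvings,
                    rate.data(), cons.data(), dx.data());
      t_cell += now_s() - tc0;
      ++n_cellsteps;
      double tm0 = now_s();

      // filopodia protrusion rule
      double f = xi[i_filo];
      f += (xi[i_v2a] > B.v2a_set) ? B.filo_ext * dt : -B.filo_ret * dt;
      if (f < 0) f = 0;
      if (f > B.filo_max) f = B.filo_max;
      xi[i_filo] = f;

      // scatter: VEGF binding/release
      double dv = xi[iv] - vsum;
      if (dv < 0 && vsum > 0) {
        double fac = 1.0 + dv / vsum;  // proportional depletion
        if (fac < 0) fac = 0;
        for (int cc = c0; cc <= c1; ++cc)
          for (int rr = r0; rr <= r1; ++rr) vegf(rr, cc) *= fac;
      } else if (dv > 0) {
        vegf(a.r, a.c) += dv;  // released at the cell surface
      }
      // scatter: sVEGFR1 export at own site
      if (xi[isv] > 0) sv(a.r, a.c) += xi[isv];
      // scatter: consumed neighbor Dll4
      double used = dnb - xi[idn];
      if (used > 0 && dnb > 0) {
        double fac = used / dnb;
        for (int k = 0; k < nnb; ++k) {
          agents[nbi[k]].x[i_dll4] -= nbshare[k] * fac;
          if (agents[nbi[k]].x[i_dll4] < 0) agents[nbi[k]].x[i_dll4] = 0;
        }
      }
      xi[iv] = 0.0; xi[isv] = 0.0; xi[isvb] = 0.0; xi[idn] = 0.0;
      for (int s = 0; s < M.n_species; ++s) a.x[s] = xi[s];

      // phenotype: strict tip criteria
      a.tip = (a.x[i_r2m] > a.x[i_r1m]) && (a.x[i_filo] > B.A_star) &&
              (a.x[i_d4m] > B.D_star);

      // movement with stalk proliferation
      if (a.tip && unif_rand() < B.move_rate * dt) {
        // direction of steepest VEGF increase within the sensing radius;
        // no gradient -> random direction
        int dir = gradient_direction_core(vegf, a.r, a.c, R);
        if (dir < 0) {
          dir = (int)(unif_rand() * 8.0); if (dir > 7) dir = 7;
        }
        // clockwise / counter-clockwise deviation
        double u = unif_rand();
        if (u < B.p_dev) dir = (dir + 1) % 8;
        else if (u < 2.0 * B.p_dev) dir = (dir + 7) % 8;

        ++mv_attempt;
        int tr = a.r + DR[dir], tc = a.c + DC[dir];
        if (tr < 0 || tr >= nr || tc < 0 || tc >= nc) ++mv_offgrid;
        else if (occ(tr, tc)) ++mv_blocked;
        if (tr >= 0 && tr < nr && tc >= 0 && tc < nc && !occ(tr, tc)) {
          // random non-tip Moore neighbor proliferates into the vacated site
          int cand[8], ncand = 0;
          for (int d = 0; d < 8; ++d) {
            int rr = a.r + DR[d], cc = a.c + DC[d];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int o = occ(rr, cc);
            if (o && !agents[o - 1].tip) cand[ncand++] = o - 1;
          }
          if (ncand == 0) ++mv_nodonor; else ++mv_ok;
          if (ncand > 0) {
            int donor = cand[(int)(unif_rand() * ncand) % ncand];
            int aidx = occ(a.r, a.c);
            int old_r = a.r, old_c = a.c;
            a.r = tr; a.c = tc;
            occ(tr, tc) = aidx;
            Agent s;
            s.id = next_id++;
            s.r = old_r; s.c = old_c; s.tip = false;
            s.x = agents[donor].x;        // duplicated state
            s.p = sample_params(mu, sd);  // freshly sampled parameters
            agents.push_back(s);
            occ(old_r, old_c) = (int)agents.size();
          }
        }
      }
      t_move += now_s() - tm0;
    }

    int ntips = 0;
    for (size_t i = 0; i < agents.size(); ++i) ntips += agents[i].tip;
    ser_t.push_back(tnow);
    ser_n.push_back((double)agents.size());
    ser_tips.push_back((double)ntips);

    while (next_snap < snap_times.size() &&
           tnow >= snap_times[next_snap] - 1e-9) {
      snapshots.push_back(take_snapshot(snap_times[next_snap]));
      ++next_snap;
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["series"] = List::create(_["time"] = ser_t, _["n_agents"] = ser_n,
                                 _["n_tips"] = ser_tips),
      _["snapshots"] = snapshots,
      _["final_fields"] = List::create(_["vegf"] = vegf, _["svegfr1"] = sv,
                                       _["svegfr1b"] = svb),
      _["n_sites"] = (double)nr * (double)nc,
      _["timing"] = NumericVector::create(
          _["fields"] = t_fields, _["gather"] = t_gather, _["cell"] = t_cell,
          _["move_scatter"] = t_move, _["n_cellsteps"] = (double)n_cellsteps),
      _["move_stats"] = NumericVector::create(
          _["attempts"] = (double)mv_attempt, _["ok"] = (double)mv_ok,
          _["blocked"] = (double)mv_blocked, _["offgrid"] = (double)mv_offgrid,
          _["no_donor"] = (double)mv_nodonor));
}

// [[Rcpp::export]]
NumericVector cpp_sample_params(NumericVector mu, NumericVector sd) {
  std::vector<double> m = as<std::vector<double>>(mu);
  std::vector<double> s = as<std::vector<double>>(sd);
  if (m.size() != s.size()) stop("mu and sd must have equal length");
  std::vector<double> out = sample_params(m, s);
  return wrap(out);
}

// Direction of steepest VEGF increase among the 8 lattice directions,
// evaluated as the mean slope along each ray over the sensing radius.
// Returns 0..7 (clockwise from north) or -1 when the field is locally
// uniform. Ties are broken uniformly at random.
// [[Rcpp::export]]
int cpp_gradient_direction(NumericMatrix vegf, int r, int c, int radius) {
  return gradient_direction_core(vegf, r, c, radius);
}

// Movement target after clockwise/counter-clockwise deviation.
// [[Rcpp::export]]
int cpp_deviate_direction(int dir, double p_dev) {
  double u = unif_rand();
  if (u < p_dev) return (dir + 1) % 8;
  if (u < 2.0 * p_dev) return (dir + 7) % 8;
  return dir;
}

// Trans-ligand available to the cell at (r, c): each occupied Moore neighbor
// contributes its dll4 amount divided by its own occupied-contact count.
// [[Rcpp::export]]
double cpp_neighbor_dll4(NumericMatrix dll4, LogicalMatrix occupied, int r,
                         int c) {
  const int nr = dll4.nrow(), nc = dll4.ncol();
  double total = 0.0;
  for (int d = 0; d < 8; ++d) {
    int rr = r + DR[d], cc = c + DC[d];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    if (!occupied(rr, cc)) continue;
    int cnt = 0;
    for (int e = 0; e < 8; ++e) {
      int r2 = rr + DR[e], c2 = cc + DC[e];
      if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && occupied(r2, c2)) ++cnt;
    }
    total += dll4(rr, cc) / std::max(1, cnt);
  }
  return total;
}
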