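// Core of the common-pool resource agent-based model.
//
// All stochastic draws use R's RNG (unif_rand / norm_rand), so seeding with
// set.seed() at the R level makes every trajectory exactly reproducible.
// State round-trips to R as a plain list; the per-site agent counts are
// rebuilt on entry so the R-side representation stays minimal.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cfg {
  int    grid_side;
  bool   torus;
  double r_growth, K_cap, D;
  double E_h, E_m, E_b;
  double harvest_fraction, energy_yield;
  double e_init, e_max, death_scale, rep_threshold, rep_prob_max;
  double w_min, w_max, z, mutation_scale, crowd_sat;
  bool   adaptive;
  int    n0;
  double rho, D_min;
};

Cfg cfg_from_list(const List& cl) {
  Cfg c;
  c.grid_side        = as<int>(cl["grid_side"]);
  c.torus            = as<bool>(cl["torus"]);
  c.r_growth         = as<double>(cl["r_growth"]);
  c.K_cap            = as<double>(cl["K_cap"]);
  c.D                = as<double>(cl["D"]);
  c.E_h              = as<double>(cl["E_h"]);
  c.E_m              = as<double>(cl["E_m"]);
  c.E_b              = as<double>(cl["E_b"]);
  c.harvest_fraction = as<double>(cl["harvest_fraction"]);
  c.energy_yield     = as<double>(cl["energy_yield"]);
  c.e_init           = as<double>(cl["e_init"]);
  c.e_max            = as<double>(cl["e_max"]);
  c.death_scale      = as<double>(cl["death_scale"]);
  c.rep_threshold    = as<double>(cl["rep_threshold"]);
  c.rep_prob_max     = as<double>(cl["rep_prob_max"]);
  c.w_min            = as<double>(cl["w_min"]);
  c.w_max            = as<double>(cl["w_max"]);
  c.z                = as<double>(cl["z"]);
  c.mutation_scale   = as<double>(cl["mutation_scale"]);
  c.crowd_sat        = as<double>(cl["crowd_sat"]);
  c.adaptive         = as<bool>(cl["adaptive"]);
  c.n0               = as<int>(cl["n0"]);
  c.rho              = as<double>(cl["rho"]);
  c.D_min            = as<double>(cl["D_min"]);
  return c;
}

struct State {
  int t;
  double D;          // current diffusion coefficient (may decay under rho)
  double next_id;
  NumericMatrix res; // grid_side x grid_side resource densities
  std::vector<double> id, en, wh, wm;
  std::vector<int> x, y; // 0-based site coordinates
  std::vector<std::vector<int> > cnt; // agents per site, rebuilt on entry
};

State state_from_list(const List& sl, int L) {
  State s;
  s.t       = as<int>(sl["t"]);
  s.D       = as<double>(sl["D"]);
  s.next_id = as<double>(sl["next_id"]);
  s.res     = as<NumericMatrix>(sl["resource"]);
  List ag   = sl["agents"];
  NumericVector id = ag["id"], en = ag["energy"], wh = ag["w_harvest"],
                wm = ag["w_move"];
  IntegerVector ax = ag["x"], ay = ag["y"];
  int n = id.size();
  s.id.assign(id.begin(), id.end());
  s.en.assign(en.begin(), en.end());
  s.wh.assign(wh.begin(), wh.end());
  s.wm.assign(wm.begin(), wm.end());
  s.x.assign(ax.begin(), ax.end());
  s.y.assign(ay.begin(), ay.end());
  s.cnt.assign(L, std::vector<int>(L, 0));
  for (int i = 0; i < n; ++i) s.cnt[s.x[i]][s.y[i]] += 1;
  return s;
}

List state_to_list(const State& s) {
  int n = s.id.size();
  NumericVector id(n), en(n), wh(n), wm(n);
  IntegerVector ax(n), ay(n);
  for (int i = 0; i < n; ++i) {
    id[i] = s.id[i]; en[i] = s.en[i]; wh[i] = s.wh[i]; wm[i] = s.wm[i];
    ax[i] = s.x[i];  ay[i] = s.y[i];
  }
  List ag = List::create(_["id"] = id, _["x"] = ax, _["y"] = ay,
                         _["energy"] = en, _["w_harvest"] = wh,
                         _["w_move"] = wm);
  return List::create(_["t"] = s.t, _["D"] = s.D, _["next_id"] = s.next_id,
                      _["resource"] = s.res, _["agents"] = ag);
}

inline int wrap(int v, int L) { return (v % L + L) % L; }

// von Neumann neighbourhood, fixed order N, E, S, W
const int DX[4] = {0, 1, 0, -1};
const int DY[4] = {-1, 0, 1, 0};

// logistic growth then explicit diffusion, clipped to [0, K]
NumericMatrix resource_step(const NumericMatrix& R0, int L, bool torus,
                            double r, double K, double D) {
  NumericMatrix G(L, L), out(L, L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      double v = R0(i, j);
      G(i, j) = v + r * v * (1.0 - v / K);
    }
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      double lap = 0.0;
      for (int d = 0; d < 4; ++d) {
        int ni = i + DX[d], nj = j + DY[d];
        if (torus) {
          ni = wrap(ni, L); nj = wrap(nj, L);
        } else if (ni < 0 || ni >= L || nj < 0 || nj >= L) {
          continue; // no-flux boundary: missing neighbour contributes nothing
        }
        lap += G(ni, nj) - G(i, j);
      }
      double v = G(i, j) + D * lap;
      if (v < 0.0) v = 0.0;
      if (v > K) v = K;
      out(i, j) = v;
    }
  return out;
}

inline double crowd_term(double count, double sat) {
  double v = count / sat;
  return v > 1.0 ? 1.0 : v;
}

// Satisfaction scores in [0,1]. High satisfaction suppresses the action.
//  A_h: hunger satisfied, little food on site, crowded site -> no harvest.
//  A_m: hunger satisfied, food here, little food next door, crowded
//       neighbours -> no move.
void satisfaction(double energy, double Rsite, const double Rnb[4],
                  const bool nb_ok[4], double cnt_others, const double cnt_nb[4],
                  const Cfg& c, double* Ah, double* Am) {
  double e_norm = c.e_max > 0 ? energy / c.e_max : 0.0;
  if (e_norm > 1.0) e_norm = 1.0;
  double r_norm = c.K_cap > 0 ? Rsite / c.K_cap : 0.0;
  if (r_norm > 1.0) r_norm = 1.0;
  double rmax_nb = 0.0, crowd_nb = 0.0;
  int nvalid = 0;
  for (int d = 0; d < 4; ++d) {
    if (!nb_ok[d]) continue;
    ++nvalid;
    double rn = c.K_cap > 0 ? Rnb[d] / c.K_cap : 0.0;
    if (rn > rmax_nb) rmax_nb = rn;
    crowd_nb += crowd_term(cnt_nb[d], c.crowd_sat);
  }
  if (nvalid > 0) crowd_nb /= nvalid;
  if (rmax_nb > 1.0) rmax_nb = 1.0;
  double crowd_here = crowd_term(cnt_others, c.crowd_sat);
  *Ah = (e_norm + (1.0 - r_norm) + crowd_here) / 3.0;
  *Am = (e_norm + r_norm + (1.0 - rmax_nb) + crowd_nb) / 4.0;
}

// action codes: 0 harvest, 1 move (dir filled in), 2 idle
int decide_action(double energy, double wh, double wm, double Rsite,
                  const double Rnb[4], const bool nb_ok[4], double cnt_others,
                  const double cnt_nb[4], const Cfg& c, int* dir) {
  double Ah, Am;
  satisfaction(energy, Rsite, Rnb, nb_ok, cnt_others, cnt_nb, c, &Ah, &Am);
  double p_h = std::exp(-wh * Ah);
  if (unif_rand() < p_h) return 0;
  double p_m = std::exp(-wm * Am);
  if (unif_rand() < p_m) {
    // target the valid neighbour with the most resource, ties uniform
    double best = -1.0;
    int ties[4], ntie = 0;
    for (int d = 0; d < 4; ++d) {
      if (!nb_ok[d]) continue;
      if (Rnb[d] > best + 1e-15) { best = Rnb[d]; ntie = 0; ties[ntie++] = d; }
      else if (std::fabs(Rnb[d] - best) <= 1e-15) { ties[ntie++] = d; }
    }
    if (ntie == 0) return 2; // isolated site (non-torus 1x1 corner cases)
    int pick = (int)std::floor(unif_rand() * ntie);
    if (pick >= ntie) pick = ntie - 1;
    *dir = ties[pick];
    return 1;
  }
  return 2;
}

void observe(const State& s, int i, int L, bool torus, double Rnb[4],
             bool nb_ok[4], double cnt_nb[4]) {
  for (int d = 0; d < 4; ++d) {
    int nx = s.x[i] + DX[d], ny = s.y[i] + DY[d];
    if (torus) {
      nx = wrap(nx, L); ny = wrap(ny, L);
    } else if (nx < 0 || nx >= L || ny < 0 || ny >= L) {
      nb_ok[d] = false; Rnb[d] = 0.0; cnt_nb[d] = 0.0;
      continue;
    }
    nb_ok[d] = true;
    Rnb[d] = s.res(nx, ny);
    cnt_nb[d] = s.cnt[nx][ny];
  }
}

inline double clip_energy(double e, double e_max) {
  if (e < 0.0) return 0.0;
  if (e > e_max) return e_max;
  return e;
}

void apply_action(State& s, int i, int action, int dir, int L, const Cfg& c) {
  if (action == 0) { // harvest
    double taken = c.harvest_fraction * s.res(s.x[i], s.y[i]);
    s.res(s.x[i], s.y[i]) -= taken;
    s.en[i] += c.energy_yield * taken - c.E_h;
  } else if (action == 1) { // move
    int nx = s.x[i] + DX[dir], ny = s.y[i] + DY[dir];
    if (c.torus) { nx = wrap(nx, L); ny = wrap(ny, L); }
    if (nx >= 0 && nx < L && ny >= 0 && ny < L) {
      s.cnt[s.x[i]][s.y[i]] -= 1;
      s.x[i] = nx; s.y[i] = ny;
      s.cnt[nx][ny] += 1;
    }
    s.en[i] -= c.E_m;
  }
  s.en[i] -= c.E_b; // basal maintenance, every step, every action
  s.en[i] = clip_energy(s.en[i], c.e_max);
}

void inherit_w(double pwh, double pwm, const Cfg& c, double* cwh, double* cwm) {
  if (c.adaptive) {
    double sd = c.mutation_scale * c.z;
    *cwh = pwh + (sd > 0 ? norm_rand() * sd : 0.0);
    *cwm = pwm + (sd > 0 ? norm_rand() * sd : 0.0);
    if (*cwh < 0) *cwh = 0;
    if (*cwm < 0) *cwm = 0;
  } else {
    *cwh = c.w_min + unif_rand() * (c.w_max - c.w_min);
    *cwm = c.w_min + unif_rand() * (c.w_max - c.w_min);
  }
}

inline double p_death(double energy, double scale) {
  if (energy <= 0.0) return 1.0;
  return std::exp(-energy / scale);
}

inline double p_repro(double energy, const Cfg& c) {
  double width = 0.1 * c.e_max;
  double u = width > 0 ? (energy - c.rep_threshold) / width
                       : (energy >= c.rep_threshold ? 50.0 : -50.0);
  return c.rep_prob_max / (1.0 + std::exp(-u));
}

void demography(State& s, int L, const Cfg& c) {
  int n = s.id.size();
  std::vector<char> alive(n, 1);
  // offspring buffered so newborns neither die nor reproduce this step
  std::vector<double> bid, ben, bwh, bwm;
  std::vector<int> bx, by;
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < p_death(s.en[i], c.death_scale)) {
      alive[i] = 0;
      s.cnt[s.x[i]][s.y[i]] -= 1;
      continue;
    }
    if (unif_rand() < p_repro(s.en[i], c)) {
      double cwh, cwm;
      inherit_w(s.wh[i], s.wm[i], c, &cwh, &cwm);
      double half = s.en[i] / 2.0;
      s.en[i] = half;
      bid.push_back(s.next_id); s.next_id += 1.0;
      ben.push_back(half); bwh.push_back(cwh); bwm.push_back(cwm);
      bx.push_back(s.x[i]); by.push_back(s.y[i]);
    }
  }
  // compact survivors in place, then append offspring
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    if (k != i) {
      s.id[k] = s.id[i]; s.en[k] = s.en[i]; s.wh[k] = s.wh[i];
      s.wm[k] = s.wm[i]; s.x[k] = s.x[i]; s.y[k] = s.y[i];
    }
    ++k;
  }
  s.id.resize(k); s.en.resize(k); s.wh.resize(k); s.wm.resize(k);
  s.x.resize(k); s.y.resize(k);
  for (size_t b = 0; b < bid.size(); ++b) {
    s.id.push_back(bid[b]); s.en.push_back(ben[b]); s.wh.push_back(bwh[b]);
    s.wm.push_back(bwm[b]); s.x.push_back(bx[b]); s.y.push_back(by[b]);
    s.cnt[bx[b]][by[b]] += 1;
  }
}

void one_step(State& s, int L, const Cfg& c) {
  s.res = resource_step(s.res, L, c.torus, c.r_growth, c.K_cap, s.D);
  int n = s.id.size();
  if (n > 0) {
    // Fisher-Yates shuffle of the update order
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double Rnb[4], cnt_nb[4];
    bool nb_ok[4];
    for (int q = 0; q < n; ++q) {
      int i = ord[q];
      observe(s, i, L, c.torus, Rnb, nb_ok, cnt_nb);
      int dir = 0;
      int act = decide_action(s.en[i], s.wh[i], s.wm[i], s.res(s.x[i], s.y[i]),
                              Rnb, nb_ok, s.cnt[s.x[i]][s.y[i]] - 1.0, cnt_nb,
                              c, &dir);
      apply_action(s, i, act, dir, L, c);
    }
  }
  demography(s, L, c);
  if (c.rho > 0) {
    s.D -= c.rho;
    if (s.D < c.D_min) s.D = c.D_min;
  }
  s.t += 1;
}

void record_row(const State& s, NumericMatrix& rec, int row) {
  int n = s.id.size();
  double swh = 0, swm = 0, sres = 0;
  for (int i = 0; i < n; ++i) { swh += s.wh[i]; swm += s.wm[i]; }
  int L = s.res.nrow();
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) sres += s.res(i, j);
  rec(row, 0) = s.t;
  rec(row, 1) = n;
  rec(row, 2) = n > 0 ? swh / n : NA_REAL;
  rec(row, 3) = n > 0 ? swm / n : NA_REAL;
  rec(row, 4) = sres;
  rec(row, 5) = s.D;
}

} // namespace

// [[Rcpp::export]]
List cpp_init_state(List cfg) {
  Cfg c = cfg_from_list(cfg);
  int L = c.grid_side;
  State s;
  s.t = 0;
  s.D = c.D;
  s.next_id = c.n0 + 1.0;
  s.res = NumericMatrix(L, L);
  std::fill(s.res.begin(), s.res.end(), c.K_cap);
  s.cnt.assign(L, std::vector<int>(L, 0));
  for (int i = 0; i < c.n0; ++i) {
    int xi = (int)std::floor(unif_rand() * L); if (xi >= L) xi = L - 1;
    int yi = (int)std::floor(unif_rand() * L); if (yi >= L) yi = L - 1;
    double whi = c.w_min + unif_rand() * (c.w_max - c.w_min);
    double wmi = c.w_min + unif_rand() * (c.w_max - c.w_min);
    s.id.push_back(i + 1.0);
    s.x.push_back(xi); s.y.push_back(yi);
    s.en.push_back(c.e_init);
    s.wh.push_back(whi); s.wm.push_back(wmi);
    s.cnt[xi][yi] += 1;
  }
  return state_to_list(s);
}

// [[Rcpp::export]]
NumericMatrix cpp_step_resource(NumericMatrix resource, bool torus,
                                double r_growth, double K_cap, double D) {
  return resource_step(resource, resource.nrow(), torus, r_growth, K_cap, D);
}

// [[Rcpp::export]]
NumericVector cpp_satisfaction(double energy, double Rsite,
                               NumericVector Rnb, LogicalVector nb_ok,
                               double cnt_others, NumericVector cnt_nb,
                               List cfg) {
  Cfg c = cfg_from_list(cfg);
  double rn[4], cn[4];
  bool ok[4];
  for (int d = 0; d < 4; ++d) { rn[d] = Rnb[d]; cn[d] = cnt_nb[d]; ok[d] = nb_ok[d]; }
  double Ah, Am;
  satisfaction(energy, Rsite, rn, ok, cnt_others, cn, c, &Ah, &Am);
  return NumericVector::create(_["A_h"] = Ah, _["A_m"] = Am);
}

// [[Rcpp::export]]
IntegerVector cpp_decide(double energy, double w_harvest, double w_move,
                         double Rsite, NumericVector Rnb, LogicalVector nb_ok,
                         double cnt_others, NumericVector cnt_nb, List cfg) {
  Cfg c = cfg_from_list(cfg);
  double rn[4], cn[4];
  bool ok[4];
  for (int d = 0; d < 4; ++d) { rn[d] = Rnb[d]; cn[d] = cnt_nb[d]; ok[d] = nb_ok[d]; }
  int dir = NA_INTEGER;
  int act = decide_action(energy, w_harvest, w_move, Rsite, rn, ok,
                          cnt_others, cn, c, &dir);
  return IntegerVector::create(_["action"] = act,
                               _["dir"] = act == 1 ? dir : NA_INTEGER);
}

// [[Rcpp::export]]
List cpp_apply_action(List state, int agent, int action, int dir, List cfg) {
  Cfg c = cfg_from_list(cfg);
  State s = state_from_list(state, c.grid_side);
  if (agent < 1 || agent > (int)s.id.size())
    stop("agent index out of range");
  apply_action(s, agent - 1, action, dir, c.grid_side, c);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_demography(List state, List cfg) {
  Cfg c = cfg_from_list(cfg);
  State s = state_from_list(state, c.grid_side);
  demography(s, c.grid_side, c);
  return state_to_list(s);
}

// [[Rcpp::export]]
NumericVector cpp_inherit(double w_harvest, double w_move, List cfg) {
  Cfg c = cfg_from_list(cfg);
  double cwh, cwm;
  inherit_w(w_harvest, w_move, c, &cwh, &cwm);
  return NumericVector::create(_["w_harvest"] = cwh, _["w_move"] = cwm);
}

// [[Rcpp::export]]
NumericVector cpp_vital_rates(NumericVector energy, List cfg) {
  Cfg c = cfg_from_list(cfg);
  int n = energy.size();
  NumericVector out(2 * n);
  for (int i = 0; i < n; ++i) {
    out[i] = p_death(energy[i], c.death_scale);
    out[n + i] = p_repro(energy[i], c);
  }
  return out;
}

// Advance n_steps; record every record_every steps (at t multiples).
// Returns the final state and the recorded rows.
// [[Rcpp::export]]
List cpp_advance(List state, List cfg, int n_steps, int record_every) {
  Cfg c = cfg_from_list(cfg);
  State s = state_from_list(state, c.grid_side);
  int nrec = 0;
  for (int k = 1; k <= n_steps; ++k)
    if ((s.t + k) % record_every == 0) ++nrec;
  NumericMatrix rec(nrec, 6);
  colnames(rec) = CharacterVector::create("t", "n", "mean_w_harvest",
                                          "mean_w_move", "total_resource", "D");
  int row = 0;
  for (int k = 1; k <= n_steps; ++k) {
    one_step(s, c.grid_side, c);
    if (s.t % record_every == 0) record_row(s, rec, row++);
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = state_to_list(s), _["records"] = rec);
}
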