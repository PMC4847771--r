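// Compiled simulation engine: one agent population advanced through the
// sense -> think -> move -> emit -> energy -> reproduce -> cull -> homeostat
// -> relocate -> age stage order, iterated.  Semantics and RNG draw order
// mirror the R reference simulation_step() exactly; R's RNG stream is used
// throughout so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

static const int NGENES = 290;
static const int NIN = 6, NHID = 10, NCTX = 10, NOUT = 3;

struct Agent {
  int id, age, birth, parent;  // parent = NA_INTEGER for founders
  bool freerider;
  std::array<double, NGENES> genes;
  std::array<double, 3> pos, vel;
  std::array<double, NCTX> ctx;
  double energy, signal;
};

static inline double sigm(double x, double beta) {
  return 1.0 / (1.0 + std::exp(-beta * x));
}

static inline double wv(double gene) { return 2.0 * gene - 1.0; }

// body frame: forward = unit velocity, up = world-z (fallback world-x)
// orthogonalised, right = forward x up
static void frame_of(const std::array<double, 3>& v, double speed,
                     double* f, double* up, double* right) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  for (int k = 0; k < 3; ++k) f[k] = v[k] / n;
  up[0] = -f[2] * f[0];
  up[1] = -f[2] * f[1];
  up[2] = 1.0 - f[2] * f[2];
  double nu = std::sqrt(up[0] * up[0] + up[1] * up[1] + up[2] * up[2]);
  if (nu < 1e-8) {
    up[0] = 1.0 - f[0] * f[0];
    up[1] = -f[0] * f[1];
    up[2] = -f[0] * f[2];
    nu = std::sqrt(up[0] * up[0] + up[1] * up[1] + up[2] * up[2]);
  }
  for (int k = 0; k < 3; ++k) up[k] /= nu;
  right[0] = f[1] * up[2] - f[2] * up[1];
  right[1] = f[2] * up[0] - f[0] * up[2];
  right[2] = f[0] * up[1] - f[1] * up[0];
  (void)speed;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List pop, NumericVector res_center, double res_reward,
                 List wcfg, List kcfg, List ccfg, List ecfg,
                 int iters, int t0, bool training, bool silenced,
                 int sample_every, bool record_agents) {
  const double L = as<double>(wcfg["arena_side"]);
  const double radius = as<double>(wcfg["sensing_radius"]);
  const double speed = as<double>(wcfg["speed"]);
  const double sense_floor = as<double>(wcfg["sense_floor"]);
  const double c1 = as<double>(kcfg["c1"]);
  const double c2 = as<double>(kcfg["c2"]);
  const double alpha_max = as<double>(kcfg["alpha_max"]);
  const double beta = as<double>(ccfg["beta"]);
  const double c_mov = as<double>(ecfg["c_mov"]);
  const double c_sig = as<double>(ecfg["c_sig_coef"]);
  const double birth_energy = as<double>(ecfg["birth_energy"]);
  const double rep_thresh = as<double>(ecfg["reproduce_threshold"]);
  const double rep_cost = as<double>(ecfg["reproduce_cost"]);
  const double max_energy = as<double>(ecfg["max_energy"]);
  const double max_absorb = as<double>(ecfg["max_absorb"]);
  const int age_cap = as<int>(ecfg["age_cap"]);
  const int pop_lo = as<int>(ecfg["pop_lo"]);
  const int pop_hi = as<int>(ecfg["pop_hi"]);
  const int pop_min = as<int>(ecfg["pop_min"]);
  const int pop_max = as<int>(ecfg["pop_max"]);
  const double cost_up = as<double>(ecfg["cost_up"]);
  const double cost_down = as<double>(ecfg["cost_down"]);
  const int res_period = as<int>(ecfg["resource_period"]);
  const double mut_rate = as<double>(ecfg["mutation_rate"]);
  const double mut_off = as<double>(ecfg["mutation_offset"]);

  // --- unpack population ---------------------------------------------------
  IntegerVector p_id = pop["id"], p_age = pop["age"], p_parent = pop["parent"],
                p_birth = pop["birth"];
  NumericMatrix p_genes = pop["genes"], p_pos = pop["pos"], p_vel = pop["vel"],
                p_ctx = pop["context"];
  NumericVector p_energy = pop["energy"], p_signal = pop["signal"];
  LogicalVector p_free = pop["freerider"];
  int next_id = as<int>(pop["next_id"]);
  double cost_factor = as<double>(pop["cost_factor"]);

  int n0 = p_id.size();
  std::vector<Agent> ag;
  ag.reserve(std::max(n0 * 2, pop_max));
  for (int i = 0; i < n0; ++i) {
    Agent a;
    a.id = p_id[i]; a.age = p_age[i]; a.birth = p_birth[i];
    a.parent = p_parent[i]; a.freerider = p_free[i];
    for (int g = 0; g < NGENES; ++g) a.genes[g] = p_genes(i, g);
    for (int k = 0; k < 3; ++k) { a.pos[k] = p_pos(i, k); a.vel[k] = p_vel(i, k); }
    for (int c = 0; c < NCTX; ++c) a.ctx[c] = p_ctx(i, c);
    a.energy = p_energy[i]; a.signal = p_signal[i];
    ag.push_back(a);
  }
  double center[3] = { res_center[0], res_center[1], res_center[2] };

  // --- logs ----------------------------------------------------------------
  std::vector<double> s_t, s_n, s_cf, s_msig, s_mdist, s_etot, s_gain, s_cost,
      s_births, s_deaths, s_removed;
  std::vector<int> b_t, b_child, b_parent, d_t, d_id, r_t;
  std::vector<double> r_x, r_y, r_z;
  std::vector<double> a_t, a_id, a_x, a_y, a_z, a_vx, a_vy, a_vz, a_sig, a_en;

  std::vector<std::array<double, 6>> inputs;
  std::vector<std::array<double, 9>> frames;  // f, up, right

  for (int step = 1; step <= iters; ++step) {
    const int t = t0 + step;
    const int n = (int)ag.size();
    int births_now = 0, deaths_now = 0;
    double gain_sum = 0, cost_sum = 0, removed_energy = 0;

    inputs.assign(n, {0, 0, 0, 0, 0, 0});
    frames.resize(n);
    for (int i = 0; i < n; ++i) {
      double f[3], up[3], right[3];
      frame_of(ag[i].vel, speed, f, up, right);
      for (int k = 0; k < 3; ++k) {
        frames[i][k] = f[k]; frames[i][3 + k] = up[k]; frames[i][6 + k] = right[k];
      }
    }

    // (1) sensing from previous positions/signals
    if (!silenced && n > 1) {
      const double r2 = radius * radius;
      for (int i = 0; i < n; ++i) {
        const double* f = &frames[i][0];
        const double* up = &frames[i][3];
        const double* right = &frames[i][6];
        for (int j = 0; j < n; ++j) {
          if (j == i || ag[j].signal <= 0) continue;
          double d[3];
          for (int k = 0; k < 3; ++k) {
            double dk = ag[j].pos[k] - ag[i].pos[k];
            dk -= L * std::nearbyint(dk / L);
            d[k] = dk;
          }
          double dist2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
          if (dist2 > r2) continue;
          double dist = std::sqrt(dist2);
          int sec = 0;
          if (dist < 1e-12) {
            sec = 0;  // coincident: front by convention
          } else {
            double df = (d[0] * f[0] + d[1] * f[1] + d[2] * f[2]) / dist;
            double dr = (d[0] * right[0] + d[1] * right[1] + d[2] * right[2]) / dist;
            double du = (d[0] * up[0] + d[1] * up[1] + d[2] * up[2]) / dist;
            double dots[6] = { df, -df, -dr, dr, du, -du };
            for (int s = 1; s < 6; ++s) if (dots[s] > dots[sec]) sec = s;
          }
          inputs[i][sec] += ag[j].signal / std::max(dist, sense_floor);
        }
        for (int s = 0; s < 6; ++s)
          if (inputs[i][s] > 1.0) inputs[i][s] = 1.0;
      }
    }

    // (2)-(4) controllers, kinematics, emitted signal
    for (int i = 0; i < n; ++i) {
      Agent& a = ag[i];
      double hid[NHID], out[NOUT], nctx[NCTX];
      for (int h = 0; h < NHID; ++h) {
        double s = 0;
        for (int j = 0; j < NIN; ++j) s += inputs[i][j] * wv(a.genes[j * NHID + h]);
        for (int c = 0; c < NCTX; ++c)
          s += a.ctx[c] * wv(a.genes[60 + c * NHID + h]);
        hid[h] = sigm(s, beta);
      }
      for (int o = 0; o < NOUT; ++o) {
        double s = 0;
        for (int h = 0; h < NHID; ++h) s += hid[h] * wv(a.genes[260 + h * NOUT + o]);
        out[o] = sigm(s, beta);
      }
      for (int c = 0; c < NCTX; ++c) {
        double s = 0;
        for (int h = 0; h < NHID; ++h) s += hid[h] * wv(a.genes[160 + h * NCTX + c]);
        nctx[c] = sigm(s, beta);
      }
      for (int c = 0; c < NCTX; ++c) a.ctx[c] = nctx[c];

      double theta = alpha_max * (2.0 * out[0] - 1.0);
      double psi = alpha_max * (2.0 * out[1] - 1.0);
      if (theta != 0 || psi != 0) {
        const double* up = &frames[i][3];
        const double* right = &frames[i][6];
        double tt = c1 * std::tan(theta), tp = c2 * std::tan(psi);
        double v2[3];
        for (int k = 0; k < 3; ++k) v2[k] = a.vel[k] + tt * right[k] + tp * up[k];
        double nv = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
        if (nv >= 1e-12)
          for (int k = 0; k < 3; ++k) a.vel[k] = v2[k] / nv * speed;
      }
      for (int k = 0; k < 3; ++k) {
        double p = a.pos[k] + a.vel[k];
        p -= L * std::floor(p / L);  // same convention as R's %%
        if (p >= L) p -= L;          // guard against rounding to exactly L
        a.pos[k] = p;
      }
      a.signal = (silenced || a.freerider) ? 0.0 : out[2];
    }

    // (5) energy ledger
    for (int i = 0; i < n; ++i) {
      Agent& a = ag[i];
      double cost = cost_factor * (c_mov + c_sig * a.signal);
      if (training) {
        double dx = a.pos[0] - center[0], dy = a.pos[1] - center[1],
               dz = a.pos[2] - center[2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double gain = (d > 0) ? res_reward / d : max_absorb;
        if (gain > max_absorb) gain = max_absorb;
        double e2 = a.energy + gain - cost;
        if (e2 > max_energy) { gain -= (e2 - max_energy); e2 = max_energy; }
        a.energy = e2;
        gain_sum += gain;
      } else {
        gain_sum += cost;  // allowance exactly covers the cost
      }
      cost_sum += cost;
    }

    if (training) {
      // (6) asynchronous reproduction (children appended, not iterated)
      for (int i = 0; i < n; ++i) {
        if (ag[i].energy < rep_thresh || (int)ag.size() >= pop_max) continue;
        Agent ch;
        double u[NGENES], off[NGENES];
        for (int g = 0; g < NGENES; ++g) u[g] = unif_rand();
        for (int g = 0; g < NGENES; ++g)
          off[g] = -mut_off + 2.0 * mut_off * unif_rand();
        for (int g = 0; g < NGENES; ++g) {
          double gv = ag[i].genes[g];
          if (u[g] < mut_rate) {
            gv += off[g];
            if (gv < 0) gv = 0; else if (gv > 1) gv = 1;
          }
          ch.genes[g] = gv;
        }
        for (int k = 0; k < 3; ++k) ch.pos[k] = L * unif_rand();
        double h[3], n2;
        do {
          for (int k = 0; k < 3; ++k) h[k] = norm_rand();
          n2 = h[0] * h[0] + h[1] * h[1] + h[2] * h[2];
        } while (n2 <= 1e-24);
        double nh = std::sqrt(n2);
        for (int k = 0; k < 3; ++k) ch.vel[k] = h[k] / nh * speed;
        for (int c = 0; c < NCTX; ++c) ch.ctx[c] = 0.5;
        ch.id = next_id++;
        ch.age = 0; ch.birth = t; ch.parent = ag[i].id;
        ch.freerider = ag[i].freerider;
        ch.energy = birth_energy; ch.signal = 0.0;
        ag[i].energy -= rep_cost;
        b_t.push_back(t); b_child.push_back(ch.id); b_parent.push_back(ag[i].id);
        ag.push_back(ch);
        ++births_now;
      }

      // (7) culling (suppressed at the population floor)
      {
        int alive = (int)ag.size();
        std::vector<Agent> keep;
        keep.reserve(alive);
        bool stop_removing = false;
        for (size_t i = 0; i < ag.size(); ++i) {
          bool dead = (ag[i].energy <= 0 || ag[i].age >= age_cap);
          if (dead && !stop_removing && alive > pop_min) {
            removed_energy += ag[i].energy;
            d_t.push_back(t); d_id.push_back(ag[i].id);
            --alive; ++deaths_now;
            if (alive <= pop_min) stop_removing = true;
          } else {
            keep.push_back(ag[i]);
          }
        }
        ag.swap(keep);
      }

      // (8) homeostat
      {
        int m = (int)ag.size();
        if (m > pop_hi) cost_factor *= cost_up;
        else if (m < pop_lo) cost_factor /= cost_down;
      }
    }

    // (9) resource relocation
    if (t % res_period == 0) {
      for (int k = 0; k < 3; ++k) center[k] = L * unif_rand();
      r_t.push_back(t); r_x.push_back(center[0]); r_y.push_back(center[1]);
      r_z.push_back(center[2]);
    }

    // (10) ageing
    for (size_t i = 0; i < ag.size(); ++i) ag[i].age += 1;

    // per-iteration aggregates
    {
      int m = (int)ag.size();
      double etot = 0, msig = 0, mdist = 0;
      for (int i = 0; i < m; ++i) {
        etot += ag[i].energy;
        msig += ag[i].signal;
        double dx = ag[i].pos[0] - center[0], dy = ag[i].pos[1] - center[1],
               dz = ag[i].pos[2] - center[2];
        mdist += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      s_t.push_back(t); s_n.push_back(m); s_cf.push_back(cost_factor);
      s_msig.push_back(m ? msig / m : NA_REAL);
      s_mdist.push_back(m ? mdist / m : NA_REAL);
      s_etot.push_back(etot);
      s_gain.push_back(gain_sum); s_cost.push_back(cost_sum);
      s_births.push_back(births_now); s_deaths.push_back(deaths_now);
      s_removed.push_back(removed_energy);
    }

    if (record_agents && (step % sample_every == 0)) {
      for (size_t i = 0; i < ag.size(); ++i) {
        a_t.push_back(t); a_id.push_back(ag[i].id);
        a_x.push_back(ag[i].pos[0]); a_y.push_back(ag[i].pos[1]);
        a_z.push_back(ag[i].pos[2]);
        a_vx.push_back(ag[i].vel[0]); a_vy.push_back(ag[i].vel[1]);
        a_vz.push_back(ag[i].vel[2]);
        a_sig.push_back(ag[i].signal); a_en.push_back(ag[i].energy);
      }
    }

    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // --- repack population ---------------------------------------------------
  int m = (int)ag.size();
  IntegerVector o_id(m), o_age(m), o_parent(m), o_birth(m);
  NumericMatrix o_genes(m, NGENES), o_pos(m, 3), o_vel(m, 3), o_ctx(m, NCTX);
  NumericVector o_energy(m), o_signal(m);
  LogicalVector o_free(m);
  for (int i = 0; i < m; ++i) {
    o_id[i] = ag[i].id; o_age[i] = ag[i].age; o_birth[i] = ag[i].birth;
    o_parent[i] = ag[i].parent; o_free[i] = ag[i].freerider;
    for (int g = 0; g < NGENES; ++g) o_genes(i, g) = ag[i].genes[g];
    for (int k = 0; k < 3; ++k) { o_pos(i, k) = ag[i].pos[k]; o_vel(i, k) = ag[i].vel[k]; }
    for (int c = 0; c < NCTX; ++c) o_ctx(i, c) = ag[i].ctx[c];
    o_energy[i] = ag[i].energy; o_signal[i] = ag[i].signal;
  }
  List out_pop = List::create(
      _["id"] = o_id, _["genes"] = o_genes, _["pos"] = o_pos, _["vel"] = o_vel,
      _["context"] = o_ctx, _["energy"] = o_energy, _["age"] = o_age,
      _["signal"] = o_signal, _["parent"] = o_parent, _["birth"] = o_birth,
      _["freerider"] = o_free, _["next_id"] = next_id,
      _["cost_factor"] = cost_factor);

  DataFrame stats = DataFrame::create(
      _["t"] = s_t, _["pop"] = s_n, _["cost_factor"] = s_cf,
      _["mean_signal"] = s_msig, _["mean_goal_dist"] = s_mdist,
      _["total_energy"] = s_etot, _["gains"] = s_gain, _["costs"] = s_cost,
      _["births"] = s_births, _["deaths"] = s_deaths,
      _["removed_energy"] = s_removed);

  List events = List::create(
      _["births"] = DataFrame::create(_["t"] = b_t, _["child"] = b_child,
                                      _["parent"] = b_parent),
      _["deaths"] = DataFrame::create(_["t"] = d_t, _["id"] = d_id),
      _["relocations"] = DataFrame::create(_["t"] = r_t, _["x"] = r_x,
                                           _["y"] = r_y, _["z"] = r_z));

  List agents = R_NilValue;
  if (record_agents) {
    agents = DataFrame::create(
        _["t"] = a_t, _["id"] = a_id, _["x"] = a_x, _["y"] = a_y,
        _["z"] = a_z, _["vx"] = a_vx, _["vy"] = a_vy, _["vz"] = a_vz,
        _["signal"] = a_sig, _["energy"] = a_en);
  }

  return List::create(
      _["population"] = out_pop,
      _["resource_center"] = NumericVector::create(center[0], center[1],
                                                   center[2]),
      _["stats"] = stats, _["events"] = events, _["agents"] = agents);
}
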