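// Clock-driven network simulation engine.
//
// Forward-Euler integration of conductance-based LIF populations at a fixed
// time step, Poisson input populations with piecewise-constant rates
// (geometric waiting-time sampling), fixed conduction delay, Tsodyks-Markram
// short-term plasticity per presynaptic neuron, and event-driven long-term
// plasticity (triplet STDP + heterosynaptic + transmitter-induced with
// consolidating reference weights on excitatory synapses; globally modulated
// pair STDP on inhibitory synapses).
//
// Update order per global step (realises the "current spike is not counted
// in the trace" convention):
//   1. deliver spikes due at this step (conductance jumps with STP scaling;
//      presynaptically triggered plasticity terms),
//   2. integrate neuron ODEs, detect threshold crossings, apply resets,
//   3. postsynaptically triggered plasticity terms on emitted spikes,
//   4. update the global secreted factor,
//   5. decay traces and add this step's spikes (traces are lazy:
//      decay-on-access, so reads in 1-3 see the pre-update values),
//   6. coarse-interval updates (reference weights, recording, NaN guard).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG (PCG32)
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() {  // in (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
};

// ------------------------------------------------------------- lazy traces
struct LazyTrace {
  std::vector<double> v;
  std::vector<long> last;
  double decay;  // per-step factor exp(-dt/tau)
  void init(int n, double dt, double tau) {
    v.assign(n, 0.0);
    last.assign(n, 0L);
    decay = std::exp(-dt / tau);
  }
  double get(int i, long step) {
    long d = step - last[i];
    if (d > 0) {
      v[i] *= std::pow(decay, (double)d);
      last[i] = step;
    }
    return v[i];
  }
  void add(int i, long step) {
    get(i, step);
    v[i] += 1.0;
  }
};

// ------------------------------------------------------------- populations
enum PopType { POP_LIF = 0, POP_POISSON = 1, POP_SPIKES = 2 };

struct StimBoundary {
  long step;
  int pattern;  // -1 = background
};

struct Population {
  int type = POP_LIF;
  int n = 0;
  bool record_spikes = false;

  // --- LIF state and parameters
  std::vector<double> U, ga, gn, gg, gad, gad2, th, I_ext;
  double tau_mem, U_rest, U_reset, theta_rest, theta_jump, tau_thr;
  double E_exc, E_inh, E_adapt;
  double d_ampa, d_gaba, d_adapt, d_adapt2, inv_tau_nmda;
  double delta_a, delta_a2, alpha;

  // --- Poisson state
  std::vector<double> base_rate, cur_rate;
  std::vector<uint32_t> gen;
  // ring buckets of (unit, gen, is_spike)
  struct Sched {
    int unit;
    uint32_t gen;
    bool is_spike;
  };
  std::vector<std::vector<Sched>> buckets;
  long horizon = 32768;
  Pcg32 *rng = nullptr;
  // stimulus
  bool has_stim = false;
  NumericMatrix zeta;  // n x P
  double stim_increment = 0.0;
  std::vector<StimBoundary> boundaries;
  size_t next_boundary = 0;

  // --- spike source
  std::vector<long> src_steps;   // sorted
  std::vector<int> src_units;
  size_t src_ptr = 0;

  // --- STP (per presynaptic neuron, shared across outgoing connections)
  bool has_stp = false;
  double stp_U, stp_tauf, stp_taud;
  std::vector<double> stp_u, stp_x;
  std::vector<long> stp_last;

  // spikes of the current step
  std::vector<int> spikes;
  std::vector<double> release;  // aligned with spikes (1.0 if no STP)

  // raster recording
  std::vector<double> rec_t;
  std::vector<int> rec_id;

  // rate recording
  long bin_count = 0;

  ~Population() { delete rng; }
};

// --------------------------------------------------------------- connections
enum ConnType { CONN_STATIC_EXC = 0, CONN_STATIC_INH = 1,
                CONN_PLASTIC_EXC = 2, CONN_PLASTIC_INH = 3 };

struct Connection {
  int src, dst, type;
  bool stp = false;
  int n_syn = 0;
  std::vector<int> pre, post;     // per synapse (original order)
  std::vector<double> w, wt;
  // CSR by presynaptic unit / CSC by postsynaptic unit
  std::vector<int> row_ptr, row_syn;
  std::vector<int> col_ptr, col_syn;

  // excitatory plasticity parameters
  double A = 0, B = 0, beta = 0, delta = 0, w_max = 5;
  bool homeostasis = false;
  double theta_ht = 1.0, b_min_frac = 0.05, tau_ht = 1200.0;
  LazyTrace z_plus, z_minus, z_slow, z_ht;
  // consolidation
  bool consol = false;
  double P = 20.0, w_P = 0.5, tau_cons = 1200.0;
  double consol_freeze_t = -1.0;  // freeze from this time on (<0: never)
  // inhibitory plasticity
  double eta = 0, tau_H = 10, gamma = 3;
  LazyTrace z_pre_i, z_post_i;
  double H = 0.0, H_decay = 1.0, H_inc = 0.0;

  long plasticity_start_step = 0;
  long clamp_count = 0;        // total clamp events
  long clamp_in_window = 0;    // since last weight record

  // recording
  long record_w_every = 0;  // in steps; 0 = off
  std::vector<int> rec_syn;  // synapse ids to track
  std::vector<double> rec_time, rec_mean_w, rec_mean_wt, rec_H;
  std::vector<long> rec_clamps;
  std::vector<std::vector<double>> rec_syn_w;

  // delivered pre units of the current step (for end-of-step trace adds)
  std::vector<int> delivered;
};

// ------------------------------------------------------------------- helpers
static double list_num(const List &l, const char *name, double def) {
  if (!l.containsElementNamed(name)) return def;
  return as<double>(l[name]);
}
static bool list_bool(const List &l, const char *name, bool def) {
  if (!l.containsElementNamed(name)) return def;
  return as<bool>(l[name]);
}

static void build_index(Connection &c, int n_pre, int n_post) {
  c.row_ptr.assign(n_pre + 1, 0);
  c.col_ptr.assign(n_post + 1, 0);
  for (int k = 0; k < c.n_syn; ++k) {
    c.row_ptr[c.pre[k] + 1]++;
    c.col_ptr[c.post[k] + 1]++;
  }
  for (int i = 0; i < n_pre; ++i) c.row_ptr[i + 1] += c.row_ptr[i];
  for (int i = 0; i < n_post; ++i) c.col_ptr[i + 1] += c.col_ptr[i];
  c.row_syn.assign(c.n_syn, 0);
  c.col_syn.assign(c.n_syn, 0);
  std::vector<int> rfill(c.row_ptr.begin(), c.row_ptr.end() - 1);
  std::vector<int> cfill(c.col_ptr.begin(), c.col_ptr.end() - 1);
  for (int k = 0; k < c.n_syn; ++k) {
    c.row_syn[rfill[c.pre[k]]++] = k;
    c.col_syn[cfill[c.post[k]]++] = k;
  }
}

// [[Rcpp::export]]
List cpp_simulate(List cfg) {
  const double dt = as<double>(cfg["dt"]);
  const double duration = as<double>(cfg["duration"]);
  const long n_steps = (long)std::llround(duration / dt);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  const double delay_s = list_num(cfg, "delay", 8e-4);
  int delay_steps = (int)std::llround(delay_s / dt);
  if (delay_steps < 1) delay_steps = 1;
  const double coarse_dt = list_num(cfg, "coarse_dt", 1.2);
  long coarse_steps = (long)std::llround(coarse_dt / dt);
  if (coarse_steps < 1) coarse_steps = 1;
  double rate_bin = 0.5;
  if (cfg.containsElementNamed("rate_bin"))
    rate_bin = as<double>(cfg["rate_bin"]);
  const long rate_bin_steps = std::max(1L, (long)std::llround(rate_bin / dt));

  List pops_cfg = cfg["populations"];
  List conns_cfg = cfg["connections"];
  const int n_pop = pops_cfg.size();
  const int n_conn = conns_cfg.size();

  List stp_cfg = cfg.containsElementNamed("stp") ? as<List>(cfg["stp"]) : List();
  const double stp_U = list_num(stp_cfg, "U", 0.2);
  const double stp_tauf = list_num(stp_cfg, "tau_f", 0.6);
  const double stp_taud = list_num(stp_cfg, "tau_d", 0.1);

  std::vector<Population> pops(n_pop);

  // ---------------------------------------------------------------- set up
  for (int p = 0; p < n_pop; ++p) {
    List pc = pops_cfg[p];
    Population &pop = pops[p];
    std::string type = as<std::string>(pc["type"]);
    pop.n = as<int>(pc["n"]);
    pop.record_spikes = list_bool(pc, "record_spikes", false);
    if (type == "lif") {
      pop.type = POP_LIF;
      List np = pc["params"];
      pop.tau_mem = list_num(np, "tau_mem", 20e-3);
      pop.U_rest = list_num(np, "U_rest", -70e-3);
      pop.U_reset = list_num(np, "U_reset", -70e-3);
      pop.theta_rest = list_num(np, "theta_rest", -50e-3);
      pop.theta_jump = list_num(np, "theta_jump", 100e-3);
      pop.tau_thr = list_num(np, "tau_thr", 5e-3);
      pop.E_exc = list_num(np, "E_exc", 0.0);
      pop.E_inh = list_num(np, "E_inh", -80e-3);
      pop.E_adapt = list_num(np, "E_adapt", -80e-3);
      double tau_ampa = list_num(np, "tau_ampa", 5e-3);
      double tau_nmda = list_num(np, "tau_nmda", 100e-3);
      double tau_gaba = list_num(np, "tau_gaba", 10e-3);
      double tau_adapt = list_num(np, "tau_adapt", 100e-3);
      double tau_adapt2 = list_num(np, "tau_adapt2", 20.0);
      pop.delta_a = list_num(np, "delta_a", 0.1);
      pop.delta_a2 = list_num(np, "delta_a2", 0.0);
      pop.alpha = list_num(np, "alpha", 0.5);
      pop.d_ampa = 1.0 - dt / tau_ampa;
      pop.d_gaba = 1.0 - dt / tau_gaba;
      pop.d_adapt = 1.0 - dt / tau_adapt;
      pop.d_adapt2 = 1.0 - dt / tau_adapt2;
      pop.inv_tau_nmda = 1.0 / tau_nmda;
      pop.U.assign(pop.n, pop.U_rest);
      pop.ga.assign(pop.n, 0.0);
      pop.gn.assign(pop.n, 0.0);
      pop.gg.assign(pop.n, 0.0);
      pop.gad.assign(pop.n, 0.0);
      pop.gad2.assign(pop.n, 0.0);
      pop.th.assign(pop.n, pop.theta_rest);
      pop.I_ext.assign(pop.n, 0.0);
      if (np.containsElementNamed("I_ext")) {
        NumericVector ie = np["I_ext"];
        if (ie.size() == 1) {
          std::fill(pop.I_ext.begin(), pop.I_ext.end(), ie[0]);
        } else {
          for (int i = 0; i < pop.n; ++i) pop.I_ext[i] = ie[i % ie.size()];
        }
      }
    } else if (type == "poisson") {
      pop.type = POP_POISSON;
      NumericVector r = pc["rate"];
      pop.base_rate.assign(pop.n, 0.0);
      for (int i = 0; i < pop.n; ++i)
        pop.base_rate[i] = r[r.size() == 1 ? 0 : i];
      pop.cur_rate = pop.base_rate;
      pop.gen.assign(pop.n, 0u);
      pop.buckets.assign((size_t)pop.horizon, {});
      pop.rng = new Pcg32(seed, (uint64_t)(1000 + p));
      if (pc.containsElementNamed("stimulus") &&
          !Rf_isNull(pc["stimulus"])) {
        List st = pc["stimulus"];
        pop.has_stim = true;
        pop.zeta = as<NumericMatrix>(st["zeta"]);
        pop.stim_increment = list_num(st, "increment", 35.0);
        IntegerVector pat = st["pattern"];
        NumericVector t0 = st["t0"], t1 = st["t1"];
        for (int k = 0; k < pat.size(); ++k) {
          StimBoundary on{(long)std::llround(t0[k] / dt), pat[k] - 1};
          StimBoundary off{(long)std::llround(t1[k] / dt), -1};
          pop.boundaries.push_back(on);
          pop.boundaries.push_back(off);
        }
      }
    } else if (type == "spike_source") {
      pop.type = POP_SPIKES;
      NumericVector t = pc["times"];
      IntegerVector id = pc["ids"];
      std::vector<size_t> ord(t.size());
      for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        return t[a] < t[b];
      });
      for (size_t i = 0; i < ord.size(); ++i) {
        pop.src_steps.push_back((long)std::llround(t[ord[i]] / dt));
        pop.src_units.push_back(id[ord[i]]);
      }
    } else {
      stop("unknown population type");
    }
  }

  std::vector<Connection> conns(n_conn);
  for (int q = 0; q < n_conn; ++q) {
    List cc = conns_cfg[q];
    Connection &c = conns[q];
    c.src = as<int>(cc["src"]) - 1;
    c.dst = as<int>(cc["dst"]) - 1;
    std::string type = as<std::string>(cc["type"]);
    if (type == "static_exc") c.type = CONN_STATIC_EXC;
    else if (type == "static_inh") c.type = CONN_STATIC_INH;
    else if (type == "plastic_exc") c.type = CONN_PLASTIC_EXC;
    else if (type == "plastic_inh") c.type = CONN_PLASTIC_INH;
    else stop("unknown connection type");
    if (c.src < 0 || c.src >= n_pop || c.dst < 0 || c.dst >= n_pop)
      stop("connection endpoints not registered");
    if (pops[c.dst].type != POP_LIF)
      stop("connection target must be a LIF population");
    IntegerVector pre = cc["pre"], post = cc["post"];
    NumericVector w = cc["w"];
    c.n_syn = pre.size();
    c.pre.assign(pre.begin(), pre.end());
    c.post.assign(post.begin(), post.end());
    c.w.assign(w.begin(), w.end());
    build_index(c, pops[c.src].n, pops[c.dst].n);
    c.stp = list_bool(cc, "stp", c.type == CONN_STATIC_EXC ||
                                  c.type == CONN_PLASTIC_EXC);
    if (c.type == CONN_STATIC_INH || c.type == CONN_PLASTIC_INH)
      c.stp = false;
    if (c.stp) {
      Population &sp = pops[c.src];
      if (!sp.has_stp) {
        sp.has_stp = true;
        sp.stp_U = stp_U;
        sp.stp_tauf = stp_tauf;
        sp.stp_taud = stp_taud;
        sp.stp_u.assign(sp.n, stp_U);
        sp.stp_x.assign(sp.n, 1.0);
        sp.stp_last.assign(sp.n, 0L);
      }
    }
    double ps = list_num(cc, "plasticity_start", 0.0);
    c.plasticity_start_step = (long)std::llround(ps / dt);
    if (c.type == CONN_PLASTIC_EXC) {
      List pp = cc["params"];
      c.A = list_num(pp, "A", 1e-3);
      c.B = list_num(pp, "B", c.A);
      c.beta = list_num(pp, "beta", 0.0);
      c.delta = list_num(pp, "delta", 0.0);
      c.w_max = list_num(pp, "w_max", 5.0);
      c.homeostasis = list_bool(pp, "homeostasis", false);
      c.theta_ht = list_num(pp, "theta_ht", 1.0);
      c.b_min_frac = list_num(pp, "b_min_frac", 0.05);
      c.tau_ht = list_num(pp, "tau_ht", 1200.0);
      c.z_plus.init(pops[c.src].n, dt, list_num(pp, "tau_plus", 20e-3));
      c.z_minus.init(pops[c.dst].n, dt, list_num(pp, "tau_minus", 20e-3));
      c.z_slow.init(pops[c.dst].n, dt, list_num(pp, "tau_slow", 100e-3));
      c.z_ht.init(pops[c.dst].n, dt, c.tau_ht);
      if (cc.containsElementNamed("wtilde") && !Rf_isNull(cc["wtilde"])) {
        NumericVector wt = cc["wtilde"];
        c.wt.assign(c.n_syn, 0.0);
        for (int k = 0; k < c.n_syn; ++k)
          c.wt[k] = wt[wt.size() == 1 ? 0 : k];
      } else {
        c.wt = c.w;
      }
      if (cc.containsElementNamed("consolidation") &&
          !Rf_isNull(cc["consolidation"])) {
        List cp = cc["consolidation"];
        c.consol = list_bool(cp, "enabled", true);
        c.P = list_num(cp, "P", 20.0);
        c.w_P = list_num(cp, "w_P", 0.5);
        c.tau_cons = list_num(cp, "tau_cons", 1200.0);
        c.consol_freeze_t = list_num(cp, "freeze_t", -1.0);
      }
    } else if (c.type == CONN_PLASTIC_INH) {
      List pp = cc["params"];
      c.eta = list_num(pp, "eta", 1e-4);
      c.tau_H = list_num(pp, "tau_H", 10.0);
      c.gamma = list_num(pp, "gamma", 3.0);
      double tau_z = list_num(pp, "tau_z", 20e-3);
      c.z_pre_i.init(pops[c.src].n, dt, tau_z);
      c.z_post_i.init(pops[c.dst].n, dt, tau_z);
      c.H = list_num(pp, "H0", 0.0);
      c.H_decay = std::exp(-dt / c.tau_H);
      c.H_inc = 1.0 / ((double)pops[c.dst].n * c.tau_H);
    }
    double rwe = list_num(cc, "record_w_every", 0.0);
    c.record_w_every = rwe > 0 ? (long)std::llround(rwe / dt) : 0;
    if (cc.containsElementNamed("record_syn") &&
        !Rf_isNull(cc["record_syn"])) {
      IntegerVector rs = cc["record_syn"];
      for (int k = 0; k < rs.size(); ++k) c.rec_syn.push_back(rs[k] - 1);
      c.rec_syn_w.assign(c.rec_syn.size(), {});
    }
  }

  // delivery ring: per population, per slot, spiking units + release factors
  const int ring_len = delay_steps + 1;
  std::vector<std::vector<std::vector<int>>> ring_units(n_pop);
  std::vector<std::vector<std::vector<double>>> ring_release(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    ring_units[p].assign(ring_len, {});
    ring_release[p].assign(ring_len, {});
  }

  // rate recording
  std::vector<std::vector<double>> rate_series(n_pop);
  std::vector<double> rate_times;

  // Poisson scheduling helper -------------------------------------------
  auto schedule_unit = [&](Population &pop, int u, long from_step) {
    double p = pop.cur_rate[u] * dt;
    if (p <= 0) return;
    if (p > 0.999999) p = 0.999999;
    double uu = pop.rng->unif();
    long k = (long)std::floor(std::log(uu) / std::log1p(-p));
    long target = from_step + k;
    bool is_spike = true;
    long park = from_step + pop.horizon - 2;
    if (target > park) {
      target = park;
      is_spike = false;
    }
    if (target >= n_steps + pop.horizon - 2) return;  // beyond simulation
    pop.buckets[(size_t)(target % pop.horizon)].push_back(
        {u, pop.gen[u], is_spike});
  };

  for (int p = 0; p < n_pop; ++p) {
    if (pops[p].type == POP_POISSON) {
      for (int u = 0; u < pops[p].n; ++u) schedule_unit(pops[p], u, 0);
    }
  }

  // ------------------------------------------------------------- main loop
  for (long step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;

    // ---- stimulus boundaries: update Poisson rates and reschedule
    for (int p = 0; p < n_pop; ++p) {
      Population &pop = pops[p];
      if (pop.type != POP_POISSON || !pop.has_stim) continue;
      bool changed = false;
      while (pop.next_boundary < pop.boundaries.size() &&
             pop.boundaries[pop.next_boundary].step <= step) {
        int pat = pop.boundaries[pop.next_boundary].pattern;
        for (int u = 0; u < pop.n; ++u) {
          pop.cur_rate[u] = pop.base_rate[u] +
              (pat >= 0 ? pop.zeta(u, pat) * pop.stim_increment : 0.0);
        }
        pop.next_boundary++;
        changed = true;
      }
      if (changed) {
        for (int u = 0; u < pop.n; ++u) {
          pop.gen[u]++;
          schedule_unit(pop, u, step);
        }
      }
    }

    // ---- source-population spike generation for this step
    for (int p = 0; p < n_pop; ++p) {
      Population &pop = pops[p];
      pop.spikes.clear();
      pop.release.clear();
      if (pop.type == POP_POISSON) {
        auto &bucket = pop.buckets[(size_t)(step % pop.horizon)];
        for (auto &e : bucket) {
          if (e.gen != pop.gen[e.unit]) continue;  // stale entry
          if (e.is_spike) {
            pop.spikes.push_back(e.unit);
            pop.gen[e.unit]++;
            schedule_unit(pop, e.unit, step + 1);
          } else {
            pop.gen[e.unit]++;
            schedule_unit(pop, e.unit, step + 1);
          }
        }
        bucket.clear();
      } else if (pop.type == POP_SPIKES) {
        while (pop.src_ptr < pop.src_steps.size() &&
               pop.src_steps[pop.src_ptr] <= step) {
          if (pop.src_steps[pop.src_ptr] == step)
            pop.spikes.push_back(pop.src_units[pop.src_ptr]);
          pop.src_ptr++;
        }
      }
    }

    // ---- 1. deliver spikes due at this step
    const int slot = (int)(step % ring_len);
    for (int q = 0; q < n_conn; ++q) {
      Connection &c = conns[q];
      Population &sp = pops[c.src];
      Population &dp = pops[c.dst];
      std::vector<int> &du = ring_units[c.src][slot];
      std::vector<double> &dr = ring_release[c.src][slot];
      if (du.empty()) continue;
      const bool is_plastic =
          (c.type == CONN_PLASTIC_EXC || c.type == CONN_PLASTIC_INH);
      const bool plastic_on = is_plastic && step >= c.plasticity_start_step;
      c.delivered.clear();
      const double G = c.H - c.gamma;
      for (size_t s = 0; s < du.size(); ++s) {
        int j = du[s];
        double r = c.stp ? dr[s] : 1.0;
        for (int kk = c.row_ptr[j]; kk < c.row_ptr[j + 1]; ++kk) {
          int k = c.row_syn[kk];
          int i = c.post[k];
          if (plastic_on) {
            if (c.type == CONN_PLASTIC_EXC) {
              double zm = c.z_minus.get(i, step);
              double Bi = c.B;
              if (c.homeostasis) {
                double nu_hat = c.z_ht.get(i, step) / c.tau_ht;
                double f = nu_hat / c.theta_ht;
                if (f > 1.0) f = 1.0;
                Bi = c.A * (c.b_min_frac + (1.0 - c.b_min_frac) * f);
              }
              double w_new = c.w[k] - Bi * zm + c.delta;
              if (w_new < 0.0) { w_new = 0.0; c.clamp_count++; c.clamp_in_window++; }
              else if (w_new > c.w_max) { w_new = c.w_max; c.clamp_count++; c.clamp_in_window++; }
              c.w[k] = w_new;
            } else {  // plastic inhibitory, pre-triggered term
              double zpost = c.z_post_i.get(i, step);
              double w_new = c.w[k] + c.eta * G * zpost;
              if (w_new < 0.0) { w_new = 0.0; c.clamp_count++; c.clamp_in_window++; }
              c.w[k] = w_new;
            }
          }
          // conductance jump
          if (c.type == CONN_STATIC_INH || c.type == CONN_PLASTIC_INH)
            dp.gg[i] += c.w[k];
          else
            dp.ga[i] += c.w[k] * r;
        }
        if (is_plastic) c.delivered.push_back(j);
      }
    }

    // ---- 2. integrate LIF populations, detect spikes
    for (int p = 0; p < n_pop; ++p) {
      Population &pop = pops[p];
      if (pop.type != POP_LIF) continue;
      const double k_m = dt / pop.tau_mem;
      for (int i = 0; i < pop.n; ++i) {
        double g_exc = pop.alpha * pop.ga[i] + (1.0 - pop.alpha) * pop.gn[i];
        double u = pop.U[i];
        u += k_m * ((pop.U_rest - u) + g_exc * (pop.E_exc - u) +
                    pop.gg[i] * (pop.E_inh - u) +
                    (pop.gad[i] + pop.gad2[i]) * (pop.E_adapt - u) +
                    pop.I_ext[i]);
        if (u < pop.E_inh) u = pop.E_inh;
        pop.gn[i] += dt * pop.inv_tau_nmda * (pop.ga[i] - pop.gn[i]);
        pop.ga[i] *= pop.d_ampa;
        pop.gg[i] *= pop.d_gaba;
        pop.gad[i] *= pop.d_adapt;
        pop.gad2[i] *= pop.d_adapt2;
        pop.th[i] += dt / pop.tau_thr * (pop.theta_rest - pop.th[i]);
        if (u >= pop.th[i]) {
          pop.spikes.push_back(i);
          u = pop.U_reset;
          pop.th[i] += pop.theta_jump;
          pop.gad[i] += pop.delta_a;
          pop.gad2[i] += pop.delta_a2;
        }
        pop.U[i] = u;
      }
    }

    // ---- STP release factors for this step's spikes (per source neuron)
    for (int p = 0; p < n_pop; ++p) {
      Population &pop = pops[p];
      if (pop.spikes.empty()) continue;
      if (pop.has_stp) {
        pop.release.resize(pop.spikes.size());
        for (size_t s = 0; s < pop.spikes.size(); ++s) {
          int u = pop.spikes[s];
          long d = step - pop.stp_last[u];
          if (d > 0) {
            double ef = std::exp(-(double)d * dt / pop.stp_tauf);
            double ed = std::exp(-(double)d * dt / pop.stp_taud);
            pop.stp_u[u] = pop.stp_U + (pop.stp_u[u] - pop.stp_U) * ef;
            pop.stp_x[u] = 1.0 + (pop.stp_x[u] - 1.0) * ed;
          }
          pop.stp_last[u] = step;
          pop.stp_u[u] += pop.stp_U * (1.0 - pop.stp_u[u]);
          double r = pop.stp_u[u] * pop.stp_x[u];
          pop.stp_x[u] -= r;
          pop.release[s] = r;
        }
      } else {
        pop.release.assign(pop.spikes.size(), 1.0);
      }
    }

    // ---- 3. postsynaptically triggered plasticity on emitted spikes
    for (int q = 0; q < n_conn; ++q) {
      Connection &c = conns[q];
      if (c.type != CONN_PLASTIC_EXC && c.type != CONN_PLASTIC_INH) continue;
      if (step < c.plasticity_start_step) continue;
      Population &dp = pops[c.dst];
      if (dp.spikes.empty()) continue;
      const double G = c.H - c.gamma;
      for (int i : dp.spikes) {
        if (c.type == CONN_PLASTIC_EXC) {
          double zm = c.z_minus.get(i, step);
          double zs = c.z_slow.get(i, step);
          double zm3 = zm * zm * zm;
          for (int kk = c.col_ptr[i]; kk < c.col_ptr[i + 1]; ++kk) {
            int k = c.col_syn[kk];
            double zp = c.z_plus.get(c.pre[k], step);
            double w_new = c.w[k] + c.A * zp * zs -
                           c.beta * (c.w[k] - c.wt[k]) * zm3;
            if (w_new < 0.0) { w_new = 0.0; c.clamp_count++; c.clamp_in_window++; }
            else if (w_new > c.w_max) { w_new = c.w_max; c.clamp_count++; c.clamp_in_window++; }
            c.w[k] = w_new;
          }
        } else {
          for (int kk = c.col_ptr[i]; kk < c.col_ptr[i + 1]; ++kk) {
            int k = c.col_syn[kk];
            double zpre = c.z_pre_i.get(c.pre[k], step);
            double w_new = c.w[k] + c.eta * G * zpre;
            if (w_new < 0.0) { w_new = 0.0; c.clamp_count++; c.clamp_in_window++; }
            c.w[k] = w_new;
          }
        }
      }
    }

    // ---- 4. global secreted factor (excludes this step's spikes from G
    //         used above; includes them from the next step on)
    for (int q = 0; q < n_conn; ++q) {
      Connection &c = conns[q];
      if (c.type != CONN_PLASTIC_INH) continue;
      c.H = c.H * c.H_decay +
            (double)pops[c.dst].spikes.size() * c.H_inc;
    }

    // ---- 5. end-of-step trace additions
    for (int q = 0; q < n_conn; ++q) {
      Connection &c = conns[q];
      if (c.type == CONN_PLASTIC_EXC) {
        for (int j : c.delivered) c.z_plus.add(j, step);
        c.delivered.clear();
        for (int i : pops[c.dst].spikes) {
          c.z_minus.add(i, step);
          c.z_slow.add(i, step);
          if (c.homeostasis) c.z_ht.add(i, step);
        }
      } else if (c.type == CONN_PLASTIC_INH) {
        for (int j : c.delivered) c.z_pre_i.add(j, step);
        c.delivered.clear();
        for (int i : pops[c.dst].spikes) c.z_post_i.add(i, step);
      }
    }

    // ---- push this step's spikes into the delivery ring, record rasters
    const int out_slot = (int)((step + delay_steps) % ring_len);
    for (int p = 0; p < n_pop; ++p) {
      Population &pop = pops[p];
      ring_units[p][out_slot] = pop.spikes;
      ring_release[p][out_slot] = pop.release;
      pop.bin_count += (long)pop.spikes.size();
      if (pop.record_spikes && !pop.spikes.empty()) {
        for (int i : pop.spikes) {
          pop.rec_t.push_back(t_now);
          pop.rec_id.push_back(i);
        }
      }
    }

    // ---- rate recording
    if ((step + 1) % rate_bin_steps == 0) {
      rate_times.push_back(t_now + dt);
      for (int p = 0; p < n_pop; ++p) {
        rate_series[p].push_back(
            (double)pops[p].bin_count /
            ((double)pops[p].n * rate_bin_steps * dt));
        pops[p].bin_count = 0;
      }
    }

    // ---- weight recording
    for (int q = 0; q < n_conn; ++q) {
      Connection &c = conns[q];
      if (c.record_w_every > 0 && (step + 1) % c.record_w_every == 0) {
        double sw = 0, swt = 0;
        for (int k = 0; k < c.n_syn; ++k) { sw += c.w[k]; }
        if (!c.wt.empty()) for (int k = 0; k < c.n_syn; ++k) swt += c.wt[k];
        c.rec_time.push_back(t_now + dt);
        c.rec_mean_w.push_back(sw / std::max(1, c.n_syn));
        c.rec_mean_wt.push_back(c.wt.empty() ? NA_REAL
                                             : swt / std::max(1, c.n_syn));
        c.rec_clamps.push_back(c.clamp_in_window);
        c.clamp_in_window = 0;
        if (c.type == CONN_PLASTIC_INH) c.rec_H.push_back(c.H);
        for (size_t s = 0; s < c.rec_syn.size(); ++s)
          c.rec_syn_w[s].push_back(c.w[c.rec_syn[s]]);
      }
    }

    // ---- 6. coarse updates
    if ((step + 1) % coarse_steps == 0) {
      const double t_next = (step + 1) * dt;
      for (int q = 0; q < n_conn; ++q) {
        Connection &c = conns[q];
        if (c.type != CONN_PLASTIC_EXC || !c.consol) continue;
        if (c.consol_freeze_t >= 0 && t_next > c.consol_freeze_t) continue;
        const double k_c = coarse_dt / c.tau_cons;
        for (int k = 0; k < c.n_syn; ++k) {
          double wt = c.wt[k];
          c.wt[k] = wt + k_c * ((c.w[k] - wt) -
                                c.P * wt * (c.w_P / 2 - wt) * (c.w_P - wt));
        }
      }
      for (int p = 0; p < n_pop; ++p) {
        Population &pop = pops[p];
        if (pop.type != POP_LIF) continue;
        for (int i = 0; i < pop.n; ++i) {
          if (!std::isfinite(pop.U[i])) {
            stop("non-finite membrane state in population %d, neuron %d, "
                 "t = %.4f s", p + 1, i, t_next);
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  // ------------------------------------------------------------- results
  List spikes_out(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    spikes_out[p] = List::create(
        _["time"] = NumericVector(pops[p].rec_t.begin(), pops[p].rec_t.end()),
        _["id"] = IntegerVector(pops[p].rec_id.begin(), pops[p].rec_id.end()));
  }
  List conns_out(n_conn);
  for (int q = 0; q < n_conn; ++q) {
    Connection &c = conns[q];
    List series = R_NilValue;
    if (c.record_w_every > 0) {
      List sl = List::create(
          _["t"] = NumericVector(c.rec_time.begin(), c.rec_time.end()),
          _["mean_w"] = NumericVector(c.rec_mean_w.begin(), c.rec_mean_w.end()),
          _["mean_wtilde"] = NumericVector(c.rec_mean_wt.begin(),
                                           c.rec_mean_wt.end()),
          _["clamps"] = NumericVector(c.rec_clamps.begin(),
                                      c.rec_clamps.end()));
      if (c.type == CONN_PLASTIC_INH)
        sl["H"] = NumericVector(c.rec_H.begin(), c.rec_H.end());
      if (!c.rec_syn.empty()) {
        NumericMatrix m(c.rec_syn_w[0].size(), c.rec_syn.size());
        for (size_t s = 0; s < c.rec_syn.size(); ++s)
          for (size_t r = 0; r < c.rec_syn_w[s].size(); ++r)
            m(r, s) = c.rec_syn_w[s][r];
        sl["syn_w"] = m;
      }
      series = sl;
    }
    conns_out[q] = List::create(
        _["pre"] = IntegerVector(c.pre.begin(), c.pre.end()),
        _["post"] = IntegerVector(c.post.begin(), c.post.end()),
        _["w"] = NumericVector(c.w.begin(), c.w.end()),
        _["wtilde"] = c.wt.empty()
            ? R_NilValue
            : (SEXP)NumericVector(c.wt.begin(), c.wt.end()),
        _["clamp_count"] = (double)c.clamp_count,
        _["H"] = c.type == CONN_PLASTIC_INH ? (SEXP)wrap(c.H)
                                            : (SEXP)R_NilValue,
        _["series"] = series);
  }
  NumericMatrix rates((int)rate_times.size(), n_pop);
  for (int p = 0; p < n_pop; ++p)
    for (size_t r = 0; r < rate_times.size(); ++r)
      rates((int)r, p) = rate_series[p][r];
  return List::create(
      _["spikes"] = spikes_out,
      _["connections"] = conns_out,
      _["rate_times"] = NumericVector(rate_times.begin(), rate_times.end()),
      _["rates"] = rates,
      _["n_steps"] = (double)n_steps);
}
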