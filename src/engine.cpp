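// Time-stepped network engine for the granular-layer simulator.
//
// Per step (phase order of the serial algorithm): due mossy-fiber spikes
// are moved into the Golgi basal and granule excitatory buffers; every
// Golgi cell consumes its buffers, advances synapses, channels, Markov
// K-AHP, calcium and Vm (including the gap current computed at the end of
// the previous step) and enqueues spikes to the granule inhibitory buffers
// with the axonal delay; gap currents are then recomputed from the fresh
// Golgi potentials; every granule cell does the same and enqueues spikes
// to the Golgi apical buffers with the ascending-axon or parallel-fiber
// delay. All delays are >= 1 step, so a spike is never consumed in its
// emission step. The engine is single-threaded and allocation-free inside
// the loop: identical inputs give bit-identical rasters.
//
// Gating steady states and decay factors exp(-dt/tau) are precomputed on a
// voltage grid and linearly interpolated (analytic evaluation is available
// behind a flag for cross-checking against the R single-cell stepper);
// calcium-dependent rates are always evaluated analytically.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

enum Form { F_EXP = 0, F_SIG, F_LINOID, F_CONST, F_CA_ON, F_CA_OFF,
            F_BIEXPINV };

struct RateLaw {
  int form = F_CONST;
  double A = 0, V0 = 0, K = 1, B = 0, A0 = 0, V1 = 0, K1 = 1, V2 = 0,
         K2 = 1;
};

static RateLaw parse_law(List l) {
  RateLaw r;
  std::string f = as<std::string>(l["form"]);
  if (f == "exponential") r.form = F_EXP;
  else if (f == "sigmoid") r.form = F_SIG;
  else if (f == "linoid") r.form = F_LINOID;
  else if (f == "constant") r.form = F_CONST;
  else if (f == "ca_on") r.form = F_CA_ON;
  else if (f == "ca_off") r.form = F_CA_OFF;
  else if (f == "bi_exp_inv") r.form = F_BIEXPINV;
  else stop("unknown rate-law form: " + f);
  if (l.containsElementNamed("A")) r.A = as<double>(l["A"]);
  if (l.containsElementNamed("V0")) r.V0 = as<double>(l["V0"]);
  if (l.containsElementNamed("K")) r.K = as<double>(l["K"]);
  if (l.containsElementNamed("B")) r.B = as<double>(l["B"]);
  if (l.containsElementNamed("A0")) r.A0 = as<double>(l["A0"]);
  if (l.containsElementNamed("V1")) r.V1 = as<double>(l["V1"]);
  if (l.containsElementNamed("K1")) r.K1 = as<double>(l["K1"]);
  if (l.containsElementNamed("V2")) r.V2 = as<double>(l["V2"]);
  if (l.containsElementNamed("K2")) r.K2 = as<double>(l["K2"]);
  return r;
}

static double eval_rate(const RateLaw &r, double v, double ca) {
  switch (r.form) {
  case F_EXP: return r.A * std::exp((v - r.V0) / r.K);
  case F_SIG: return r.A / (1.0 + std::exp((v - r.V0) / r.K));
  case F_LINOID: {
    double x = (v - r.V0) / r.K;
    if (std::fabs(x) < 1e-6) return r.A * r.K * (1.0 - x / 2.0);
    return r.A * (v - r.V0) / (std::exp(x) - 1.0);
  }
  case F_CONST: return r.A;
  case F_CA_ON: return r.A / (1.0 + r.B * std::exp(v / r.K) / ca);
  case F_CA_OFF: return r.A / (1.0 + ca / (r.B * std::exp(v / r.K)));
  default: stop("rate law form not valid here");
  }
  return 0;
}

static double eval_tau(const RateLaw &r, double v) {
  switch (r.form) {
  case F_CONST: return r.A;
  case F_EXP: return r.A * std::exp((v - r.V0) / r.K);
  case F_BIEXPINV:
    return r.A0 + r.A / (std::exp((v - r.V1) / r.K1) +
                         std::exp((v - r.V2) / r.K2));
  default: stop("tau law form not valid here");
  }
  return 0;
}

struct Gate {
  int power = 1;
  bool alpha_beta = true;
  bool ca_dep = false;       // calcium-dependent rates: no table
  RateLaw a, b, inf, tau;
  // lookup tables (non-ca gates)
  std::vector<double> tb_inf, tb_dec;
};

struct Channel {
  double gbar = 0, erev = 0, q10f = 1;
  bool dyn_ca = false;
  std::vector<Gate> gates;
};

struct Markov {
  double gbar = 0, erev = 0;
  int n = 0;
  std::vector<int> open, from, to;
  std::vector<double> base, camult;
};

struct CellModel {
  double cm = 1, area = 1, thr = -20, min_isi = 1, v_init = -70;
  double ca_depth = 0.2, ca_beta = 1.5, ca0 = 1e-4, cao = 2, tempK = 303.15;
  std::vector<Channel> ch;
  bool has_markov = false;
  Markov mk;
  int n_gates = 0;
};

static const double VMIN = -120.0, VMAX = 80.0, VSTEP = 0.02;
static const int NV = (int)((VMAX - VMIN) / VSTEP) + 1;
static const double FARADAY = 96485.33212, RGAS = 8.31446262;

static void gate_inf_tau(const Gate &g, double q10f, double v, double ca,
                         double &inf, double &tau) {
  if (g.alpha_beta) {
    double a = eval_rate(g.a, v, ca) * q10f;
    double b = eval_rate(g.b, v, ca) * q10f;
    double s = a + b;
    inf = a / s;
    tau = 1.0 / s;
  } else {
    inf = eval_rate(g.inf, v, ca);
    tau = eval_tau(g.tau, v) / q10f;
    if (tau < 1e-6) tau = 1e-6;
  }
}

static CellModel parse_cell(List m, double dt) {
  CellModel cm;
  cm.cm = as<double>(m["cm_pF"]);
  cm.area = as<double>(m["area_um2"]);
  cm.thr = as<double>(m["spike_threshold"]);
  cm.min_isi = as<double>(m["min_isi"]);
  cm.v_init = as<double>(m["v_init"]);
  cm.tempK = as<double>(m["temperature_K"]);
  List cal = m["calcium"];
  cm.ca_depth = as<double>(cal["depth_um"]);
  cm.ca_beta = as<double>(cal["beta_ms"]);
  cm.ca0 = as<double>(cal["ca0_mM"]);
  cm.cao = as<double>(cal["cao_mM"]);
  List chans = m["channels"];
  for (int i = 0; i < chans.size(); ++i) {
    List c = chans[i];
    Channel ch;
    ch.gbar = as<double>(c["gbar"]);
    ch.dyn_ca = as<bool>(c["dynamic_ca"]);
    ch.erev = ch.dyn_ca ? 0.0 : as<double>(c["erev"]);
    ch.q10f = as<double>(c["q10f"]);
    List gl = c["gates"];
    for (int j = 0; j < gl.size(); ++j) {
      List gd = gl[j];
      Gate g;
      g.power = as<int>(gd["power"]);
      std::string kind = as<std::string>(gd["kind"]);
      g.alpha_beta = (kind == "alpha_beta");
      if (g.alpha_beta) {
        g.a = parse_law(gd["alpha"]);
        g.b = parse_law(gd["beta"]);
        g.ca_dep = (g.a.form == F_CA_ON || g.a.form == F_CA_OFF ||
                    g.b.form == F_CA_ON || g.b.form == F_CA_OFF);
      } else {
        g.inf = parse_law(gd["inf"]);
        g.tau = parse_law(gd["tau"]);
      }
      if (!g.ca_dep) {   // precompute tables
        g.tb_inf.resize(NV);
        g.tb_dec.resize(NV);
        for (int k = 0; k < NV; ++k) {
          double v = VMIN + k * VSTEP, inf, tau;
          gate_inf_tau(g, ch.q10f, v, 1e-4, inf, tau);
          g.tb_inf[k] = inf;
          g.tb_dec[k] = std::exp(-dt / tau);
        }
      }
      cm.n_gates++;
      ch.gates.push_back(g);
    }
    cm.ch.push_back(ch);
  }
  if (m.containsElementNamed("markov") &&
      !Rf_isNull(m["markov"])) {
    List mk = m["markov"];
    cm.has_markov = true;
    cm.mk.gbar = as<double>(mk["gbar"]);
    cm.mk.erev = as<double>(mk["erev"]);
    cm.mk.n = as<CharacterVector>(mk["states"]).size();
    IntegerVector op = mk["open"], fr = mk["from"], to = mk["to"];
    NumericVector rb = mk["rate_base"], rc = mk["rate_ca"];
    for (int i = 0; i < op.size(); ++i) cm.mk.open.push_back(op[i] - 1);
    for (int i = 0; i < fr.size(); ++i) {
      cm.mk.from.push_back(fr[i] - 1);
      cm.mk.to.push_back(to[i] - 1);
      cm.mk.base.push_back(rb[i]);
      cm.mk.camult.push_back(rc[i]);
    }
  }
  return cm;
}

struct Scheme {
  double gmax = 0, vrev = 0;
  bool mg = false;
  int n = 0;
  std::vector<int> open, from, to;
  std::vector<double> base, tmult;
};

static Scheme parse_scheme(List s) {
  Scheme sc;
  sc.gmax = as<double>(s["gmax_nS"]);
  sc.vrev = as<double>(s["vrev"]);
  sc.mg = as<bool>(s["mg_block"]);
  sc.n = as<CharacterVector>(s["states"]).size();
  IntegerVector op = s["open"], fr = s["from"], to = s["to"];
  NumericVector rb = s["rate_base"], rt = s["rate_t"];
  for (int i = 0; i < op.size(); ++i) sc.open.push_back(op[i] - 1);
  for (int i = 0; i < fr.size(); ++i) {
    sc.from.push_back(fr[i] - 1);
    sc.to.push_back(to[i] - 1);
    sc.base.push_back(rb[i]);
    sc.tmult.push_back(rt[i]);
  }
  return sc;
}

struct Presyn { double u, tau_rec, tau_in, tmax, tdur; };
struct MgBlock { double mg, slope, k; };

// Pool of identical synapses (one scheme set), structure-of-arrays. The
// transition lists of all schemes are flattened into one array whose
// from/to indices address the per-synapse occupancy block directly.
struct SynPool {
  std::vector<const Scheme *> schemes;
  Presyn ps;
  MgBlock mg;
  int n = 0, tot_states = 0, n_trans = 0;
  std::vector<int> t_from, t_to;                // block-relative indices
  std::vector<double> t_base, t_tmult;
  std::vector<int> sch_off, rest_idx;           // per-scheme state offset
  std::vector<double> x, y, z, since_rel;
  std::vector<double> occ;                      // n * tot_states
  std::vector<uint8_t> active;

  void init(int n_, std::vector<const Scheme *> sch, Presyn p, MgBlock m) {
    n = n_;
    schemes = sch;
    ps = p;
    mg = m;
    tot_states = 0;
    for (auto s : schemes) {
      sch_off.push_back(tot_states);
      rest_idx.push_back(tot_states);
      for (size_t t = 0; t < s->from.size(); ++t) {
        t_from.push_back(tot_states + s->from[t]);
        t_to.push_back(tot_states + s->to[t]);
        t_base.push_back(s->base[t]);
        t_tmult.push_back(s->tmult[t]);
      }
      tot_states += s->n;
    }
    n_trans = (int)t_from.size();
    x.assign(n, 1.0); y.assign(n, 0.0); z.assign(n, 0.0);
    since_rel.assign(n, 1e18);
    occ.assign((size_t)n * tot_states, 0.0);
    for (int i = 0; i < n; ++i)
      for (int r : rest_idx) occ[(size_t)i * tot_states + r] = 1.0;
    active.assign(n, 0);
  }

  // advance synapse i; returns current at membrane potential vm
  double step(int i, bool spike_now, double vm, double dt) {
    if (!active[i] && !spike_now) return 0.0;
    if (spike_now) {
      double rel = ps.u * x[i];
      x[i] -= rel;
      y[i] += rel;
      since_rel[i] = 0.0;
      active[i] = 1;
    } else {
      since_rel[i] += dt;
    }
    double dy = y[i] / ps.tau_in, dz = z[i] / ps.tau_rec;
    y[i] -= dt * dy;
    z[i] += dt * (dy - dz);
    x[i] += dt * dz;
    double T = (since_rel[i] < ps.tdur) ? ps.tmax : 0.0;
    double *o = &occ[(size_t)i * tot_states];
    // fluxes evaluated on the pre-update occupancies (first-order Euler
    // of the master equation), then applied
    double flux[64];
    if (T > 0.0) {
      for (int t = 0; t < n_trans; ++t)
        flux[t] = o[t_from[t]] * (t_base[t] + t_tmult[t] * T) * dt;
    } else {
      for (int t = 0; t < n_trans; ++t)
        flux[t] = o[t_from[t]] * t_base[t] * dt;
    }
    for (int t = 0; t < n_trans; ++t) {
      o[t_from[t]] -= flux[t];
      o[t_to[t]] += flux[t];
    }
    double itot = 0.0;
    for (size_t si = 0; si < schemes.size(); ++si) {
      const Scheme *s = schemes[si];
      double po = 0.0;
      for (int k : s->open) po += o[sch_off[si] + k];
      double icur = s->gmax * po * (vm - s->vrev);
      if (s->mg)
        icur *= 1.0 / (1.0 + std::exp(-mg.slope * vm) * mg.mg / mg.k);
      itot += icur;
    }
    // snap back to rest when fully decayed (skips silent synapses);
    // only worth probing long after the last release event
    if (T == 0.0 && since_rel[i] > 200.0) {
      double resid = 0.0;
      for (size_t si = 0; si < schemes.size(); ++si)
        for (int k = 1; k < schemes[si]->n; ++k)
          resid += o[sch_off[si] + k];
      if (resid < 1e-9 && 1.0 - x[i] < 1e-9) {
        x[i] = 1.0; y[i] = 0.0; z[i] = 0.0;
        for (int k = 0; k < tot_states; ++k) o[k] = 0.0;
        for (int r : rest_idx) o[r] = 1.0;
        active[i] = 0;
      }
    }
    return itot;
  }
};

// One cell population, structure-of-arrays.
struct Pop {
  const CellModel *m;
  int n = 0;
  bool use_tables = true;
  std::vector<double> vm, ca, eca, last_spike;
  std::vector<double> gates;       // n * n_gates
  std::vector<double> mkocc;       // n * mk.n

  void init(const CellModel *mm, int n_, bool tables) {
    m = mm; n = n_; use_tables = tables;
    vm.assign(n, m->v_init);
    ca.assign(n, m->ca0);
    double e0 = 1000.0 * RGAS * m->tempK / (2.0 * FARADAY) *
                std::log(m->cao / m->ca0);
    eca.assign(n, e0);
    last_spike.assign(n, -1e18);
    gates.assign((size_t)n * m->n_gates, 0.0);
    for (int i = 0; i < n; ++i) {
      size_t gi = (size_t)i * m->n_gates;
      for (const auto &ch : m->ch)
        for (const auto &g : ch.gates) {
          double inf, tau;
          gate_inf_tau(g, ch.q10f, m->v_init, m->ca0, inf, tau);
          gates[gi++] = inf;
        }
    }
    if (m->has_markov) {
      mkocc.assign((size_t)n * m->mk.n, 0.0);
      for (int i = 0; i < n; ++i) mkocc[(size_t)i * m->mk.n] = 1.0;
    }
  }

  // advance cell i one Euler step; returns true when it spikes
  bool step(int i, double i_syn, double i_gap, double dt, double t_now) {
    double v = vm[i];
    double cai = ca[i];
    double i_total = 0.0, i_ca = 0.0;
    size_t gi = (size_t)i * m->n_gates;
    double vc = v < VMIN ? VMIN : (v > VMAX ? VMAX : v);
    double fid = (vc - VMIN) / VSTEP;
    int i0 = (int)fid;
    if (i0 >= NV - 1) i0 = NV - 2;
    double fr = fid - i0;
    for (const auto &ch : m->ch) {
      double g = ch.gbar;
      for (const auto &gd : ch.gates) {
        double gv = gates[gi];
        double inf, dec;
        if (use_tables && !gd.ca_dep) {
          inf = gd.tb_inf[i0] + (gd.tb_inf[i0 + 1] - gd.tb_inf[i0]) * fr;
          dec = gd.tb_dec[i0] + (gd.tb_dec[i0 + 1] - gd.tb_dec[i0]) * fr;
        } else {
          double tau;
          gate_inf_tau(gd, ch.q10f, v, cai, inf, tau);
          dec = std::exp(-dt / tau);
        }
        gv = inf - (inf - gv) * dec;
        gates[gi] = gv;
        ++gi;
        switch (gd.power) {
        case 1: g *= gv; break;
        case 2: g *= gv * gv; break;
        case 3: g *= gv * gv * gv; break;
        case 4: { double g2 = gv * gv; g *= g2 * g2; } break;
        default: g *= std::pow(gv, gd.power);
        }
      }
      double e = ch.dyn_ca ? eca[i] : ch.erev;
      double icur = g * (v - e);
      i_total += icur;
      if (ch.dyn_ca) i_ca += icur;
    }
    if (m->has_markov) {
      double *o = &mkocc[(size_t)i * m->mk.n];
      double sum = 0.0;
      double flux[32];
      size_t ntr = m->mk.from.size();
      for (size_t t = 0; t < ntr; ++t) {
        double rate = m->mk.base[t] + m->mk.camult[t] * cai;
        flux[t] = o[m->mk.from[t]] * rate * dt;
      }
      for (size_t t = 0; t < ntr; ++t) {
        o[m->mk.from[t]] -= flux[t];
        o[m->mk.to[t]] += flux[t];
      }
      for (int k = 0; k < m->mk.n; ++k) sum += o[k];
      for (int k = 0; k < m->mk.n; ++k) o[k] /= sum;
      double po = 0.0;
      for (int k : m->mk.open) po += o[k];
      i_total += m->mk.gbar * po * (v - m->mk.erev);
    }
    // calcium shell + Nernst potential
    double influx = -i_ca * 1e3 / (2.0 * FARADAY * m->area * m->ca_depth);
    double ca_new = cai + dt * (influx - m->ca_beta * (cai - m->ca0));
    if (ca_new < 0) ca_new = 0;
    ca[i] = ca_new;
    double ca_eff = ca_new > 1e-12 ? ca_new : 1e-12;
    eca[i] = 1000.0 * RGAS * m->tempK / (2.0 * FARADAY) *
             std::log(m->cao / ca_eff);
    double v_new = v + dt * (-i_syn - i_gap - i_total) / m->cm;
    if (!std::isfinite(v_new))
      stop("numerical divergence in cell %d at t = %.3f ms", i + 1, t_now);
    bool spiked = (v < m->thr && v_new >= m->thr &&
                   (t_now + dt) - last_spike[i] >= m->min_isi);
    vm[i] = v_new;
    if (spiked) last_spike[i] = t_now + dt;
    return spiked;
  }
};

// flattened adjacency passed from R: ptr (n_src + 1, 0-based), targets
struct FlatAdj {
  IntegerVector ptr, tgt, tag;
  bool has_tag = false;
};

static FlatAdj get_adj(List net, const char *name) {
  FlatAdj a;
  List l = net[name];
  a.ptr = l["ptr"];
  a.tgt = l["targets"];
  if (l.containsElementNamed("tag") && !Rf_isNull(l["tag"])) {
    a.tag = l["tag"];
    a.has_tag = true;
  }
  return a;
}

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List net, List grc_model, List goc_model, List syn_model,
                IntegerVector sched_step, IntegerVector sched_mf,
                List params) {
  const double dt = as<double>(params["dt"]);
  const int n_steps = as<int>(params["n_steps"]);
  const double g_gap = as<double>(params["g_gap"]);
  const bool use_tables = as<bool>(params["use_tables"]);
  const int d_mf = as<int>(params["delay_mf_steps"]);
  const int d_goc = as<int>(params["delay_goc_steps"]);
  const int d_aa = as<int>(params["delay_aa_steps"]);
  const int d_pf = as<int>(params["delay_pf_steps"]);
  if (d_mf < 1 || d_goc < 1 || d_aa < 1 || d_pf < 1)
    stop("delays must be at least one time step");

  const int n_goc = as<int>(net["n_goc"]);
  const int n_grc = as<int>(net["n_grc"]);

  CellModel grc_cm = parse_cell(grc_model, dt);
  CellModel goc_cm = parse_cell(goc_model, dt);

  // synapse schemes
  List rec = syn_model["schemes_exc"];
  Scheme ampa = parse_scheme(rec["ampa"]);
  Scheme nmda = parse_scheme(rec["nmda"]);
  List rec2 = syn_model["schemes_inh"];
  Scheme gab1 = parse_scheme(rec2["gaba_a1"]);
  Scheme gab6 = parse_scheme(rec2["gaba_a6"]);
  List psl = syn_model["presyn"];
  Presyn ps{as<double>(psl["u"]), as<double>(psl["tau_rec_ms"]),
            as<double>(psl["tau_in_ms"]), as<double>(psl["t_max_mM"]),
            as<double>(psl["t_dur_ms"])};
  List mgl = syn_model["mg"];
  MgBlock mg{as<double>(mgl["mg_mM"]), as<double>(mgl["slope_per_mV"]),
             as<double>(mgl["k_mM"])};

  std::vector<const Scheme *> exc_sch{&ampa, &nmda};
  std::vector<const Scheme *> inh_sch{&gab1, &gab6};

  Pop grc, goc;
  grc.init(&grc_cm, n_grc, use_tables);
  goc.init(&goc_cm, n_goc, use_tables);

  SynPool grc_exc, grc_inh, goc_exc, goc_inh;
  grc_exc.init(n_grc * 4, exc_sch, ps, mg);
  grc_inh.init(n_grc * 4, inh_sch, ps, mg);
  goc_exc.init(n_goc * 2, exc_sch, ps, mg);   // 0: basal, 1: apical
  goc_inh.init(n_goc, inh_sch, ps, mg);

  // fan-out maps (0-based ids from R)
  FlatAdj mf_grc = get_adj(net, "mf_grc");     // MF -> grc dendrite slot
  FlatAdj mf_gocb = get_adj(net, "mf_gocb");   // MF -> GOC (basal)
  FlatAdj goc_grc = get_adj(net, "goc_grc");   // GOC -> grc dendrite slot
  FlatAdj grc_goc_map = get_adj(net, "grc_goc"); // GRC -> GOC (tag 1 aa, 2 pf)
  FlatAdj gap = get_adj(net, "gap");           // GOC -> GOC

  // ring buffers of pending spike counts
  int horizon = std::max(std::max(d_mf, d_goc), std::max(d_aa, d_pf)) + 1;
  std::vector<uint16_t> q_grc_exc((size_t)n_grc * 4 * horizon, 0);
  std::vector<uint16_t> q_grc_inh((size_t)n_grc * 4 * horizon, 0);
  std::vector<uint16_t> q_goc_bas((size_t)n_goc * horizon, 0);
  std::vector<uint16_t> q_goc_api((size_t)n_goc * horizon, 0);
  std::vector<uint16_t> q_goc_inh((size_t)n_goc * horizon, 0);

  std::vector<double> i_gap_prev(n_goc, 0.0);  // zero at t = 0: equal Vm

  // recording
  IntegerVector rec_goc = params["record_goc"];
  IntegerVector rec_grc = params["record_grc"];
  const int stride = as<int>(params["record_stride"]);
  int n_rec_steps = (stride > 0) ? (n_steps + stride - 1) / stride : 0;
  NumericMatrix tr_goc(n_rec_steps, rec_goc.size());
  NumericMatrix tr_grc(n_rec_steps, rec_grc.size());

  std::vector<int> ras_class, ras_id;
  std::vector<double> ras_t;
  long long delivered = 0, consumed = 0, mf_emitted = 0;

  int sp = 0;                   // schedule pointer
  const int n_sched = sched_step.size();

  for (int t = 0; t < n_steps; ++t) {
    const double t_now = t * dt;
    const int slot_now = t % horizon;

    // 1. mossy-fiber spikes emitted this step -> buffers at t + d_mf
    while (sp < n_sched && sched_step[sp] == t) {
      int mf = sched_mf[sp];
      ++mf_emitted;
      int slot = (t + d_mf) % horizon;
      for (int k = mf_grc.ptr[mf]; k < mf_grc.ptr[mf + 1]; ++k) {
        q_grc_exc[(size_t)mf_grc.tgt[k] * horizon + slot]++;
        ++delivered;
      }
      for (int k = mf_gocb.ptr[mf]; k < mf_gocb.ptr[mf + 1]; ++k) {
        q_goc_bas[(size_t)mf_gocb.tgt[k] * horizon + slot]++;
        ++delivered;
      }
      ++sp;
    }
    if (sp < n_sched && sched_step[sp] < t)
      stop("schedule not sorted by step");

    // 2. Golgi cells
    for (int i = 0; i < n_goc; ++i) {
      double i_syn = 0.0;
      uint16_t &cb = q_goc_bas[(size_t)i * horizon + slot_now];
      bool sb = cb > 0; consumed += cb; cb = 0;
      i_syn += goc_exc.step(2 * i, sb, goc.vm[i], dt);
      uint16_t &ca_ = q_goc_api[(size_t)i * horizon + slot_now];
      bool sa = ca_ > 0; consumed += ca_; ca_ = 0;
      i_syn += goc_exc.step(2 * i + 1, sa, goc.vm[i], dt);
      uint16_t &ci = q_goc_inh[(size_t)i * horizon + slot_now];
      bool si = ci > 0; consumed += ci; ci = 0;
      i_syn += goc_inh.step(i, si, goc.vm[i], dt);
      bool spiked = goc.step(i, i_syn, i_gap_prev[i], dt, t_now);
      if (spiked) {
        ras_class.push_back(0);
        ras_id.push_back(i + 1);
        ras_t.push_back(t_now + dt);
        int slot = (t + d_goc) % horizon;
        for (int k = goc_grc.ptr[i]; k < goc_grc.ptr[i + 1]; ++k) {
          q_grc_inh[(size_t)goc_grc.tgt[k] * horizon + slot]++;
          ++delivered;
        }
      }
    }

    // 3. gap-junction currents from the fresh Golgi potentials
    for (int i = 0; i < n_goc; ++i) {
      double s = 0.0;
      for (int k = gap.ptr[i]; k < gap.ptr[i + 1]; ++k)
        s += goc.vm[i] - goc.vm[gap.tgt[k]];
      i_gap_prev[i] = g_gap * s;
    }

    // 4. granule cells
    for (int i = 0; i < n_grc; ++i) {
      double i_syn = 0.0;
      for (int d = 0; d < 4; ++d) {
        size_t q = ((size_t)i * 4 + d) * horizon + slot_now;
        uint16_t &ce = q_grc_exc[q];
        bool se = ce > 0; consumed += ce; ce = 0;
        i_syn += grc_exc.step(i * 4 + d, se, grc.vm[i], dt);
        uint16_t &ci = q_grc_inh[q];
        bool si = ci > 0; consumed += ci; ci = 0;
        i_syn += grc_inh.step(i * 4 + d, si, grc.vm[i], dt);
      }
      bool spiked = grc.step(i, i_syn, 0.0, dt, t_now);
      if (spiked) {
        ras_class.push_back(1);
        ras_id.push_back(i + 1);
        ras_t.push_back(t_now + dt);
        for (int k = grc_goc_map.ptr[i]; k < grc_goc_map.ptr[i + 1]; ++k) {
          int dstep = (grc_goc_map.has_tag && grc_goc_map.tag[k] == 2)
                          ? d_pf : d_aa;
          int slot = (t + dstep) % horizon;
          q_goc_api[(size_t)grc_goc_map.tgt[k] * horizon + slot]++;
          ++delivered;
        }
      }
    }

    // 5. record
    if (stride > 0 && t % stride == 0) {
      int row = t / stride;
      for (int k = 0; k < rec_goc.size(); ++k)
        tr_goc(row, k) = goc.vm[rec_goc[k] - 1];
      for (int k = 0; k < rec_grc.size(); ++k)
        tr_grc(row, k) = grc.vm[rec_grc[k] - 1];
    }
    if (t % 4000 == 0) Rcpp::checkUserInterrupt();
  }

  long long pending = 0;
  for (auto v : q_grc_exc) pending += v;
  for (auto v : q_grc_inh) pending += v;
  for (auto v : q_goc_bas) pending += v;
  for (auto v : q_goc_api) pending += v;
  for (auto v : q_goc_inh) pending += v;

  return List::create(
      _["raster_class"] = wrap(ras_class), _["raster_id"] = wrap(ras_id),
      _["raster_t"] = wrap(ras_t), _["vm_goc"] = tr_goc,
      _["vm_grc"] = tr_grc, _["mf_spikes_emitted"] = (double)mf_emitted,
      _["events_delivered"] = (double)delivered,
      _["events_consumed"] = (double)consumed,
      _["events_pending"] = (double)pending,
      _["final_vm_goc"] = wrap(goc.vm), _["final_vm_grc"] = wrap(grc.vm));
}
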