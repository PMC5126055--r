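#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Self-contained counter-free RNG for the simulation core: xoroshiro128+
// seeded through splitmix64.  Keeps trial dynamics deterministic under an
// integer seed independently of the R session RNG state.
namespace {

struct Xoro {
  uint64_t s0, s1;
  bool have_norm;
  double cached_norm;

  explicit Xoro(uint64_t seed) : have_norm(false), cached_norm(0.0) {
    uint64_t z = seed;
    uint64_t out[2];
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      out[i] = t ^ (t >> 31);
    }
    s0 = out[0];
    s1 = out[1] ? out[1] : 0x9e3779b97f4a7c15ULL;
  }

  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }

  inline double unif() {
    // 53-bit mantissa uniform in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {
    if (have_norm) {
      have_norm = false;
      return cached_norm;
    }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    cached_norm = r * std::sin(th);
    have_norm = true;
    return r * std::cos(th);
  }
};

struct Nucleus {
  std::vector<double> v, u;
  double a, b, c, d, vpeak, bias;
  std::vector<int> spike;  // spikes on the most recent step (0/1)

  void init(int n, NumericVector p, Xoro &rng, double jitter) {
    a = p["a"]; b = p["b"]; c = p["c"]; d = p["d"];
    vpeak = p["v_peak"]; bias = p["bias"];
    v.assign(n, 0.0);
    u.assign(n, 0.0);
    spike.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      v[i] = c + jitter * rng.unif();
      u[i] = b * v[i];
    }
  }

  // Simultaneous forward-Euler update from (v,u), then threshold reset.
  inline void step(const std::vector<double> &I, double dt) {
    const int n = (int)v.size();
    for (int i = 0; i < n; ++i) {
      double vo = v[i], uo = u[i];
      double vn = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 - uo + I[i]);
      double un = uo + dt * (a * (b * vo - uo));
      if (vn >= vpeak) {
        spike[i] = 1;
        vn = c;
        un += d;
      } else {
        spike[i] = 0;
      }
      v[i] = vn;
      u[i] = un;
    }
  }
};

// 4-neighbour (von Neumann) sum of a lattice field, zero-flux boundary.
inline void neighbour_sum(const std::vector<double> &x, int nr, int nc,
                          std::vector<double> &out) {
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = i + nr * j;
      double s = 0.0;
      if (i > 0) s += x[k - 1];
      if (i < nr - 1) s += x[k + 1];
      if (j > 0) s += x[k - nr];
      if (j < nc - 1) s += x[k + nr];
      out[k] = s;
    }
  }
}

inline double dbs_polarity(double t, double period, double pw) {
  double m = t - period * std::floor(t / period);
  // guard against fmod landing exactly on period due to rounding
  if (m >= period) m -= period;
  if (m < pw) return 1.0;
  if (m < 2.0 * pw) return -1.0;
  return 0.0;
}

}  // namespace

// Core integration loop shared by open-loop population simulations and
// single IGT trials (race model enabled).  All connectivity is one-to-one
// between corresponding lattice positions plus 4-neighbour lateral kernels
// within STN and GPe.  Gains are magnitudes; signs (anatomy) are explicit
// in the current assembly below.
// [[Rcpp::export(name = ".bg_engine")]]
List bg_engine(List cfg) {
  const int nr = as<int>(cfg["rows"]);
  const int nc = as<int>(cfg["cols"]);
  const int n = nr * nc;
  const double dt = as<double>(cfg["dt"]);
  const int nsteps = as<int>(cfg["n_steps"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);

  Xoro rng(seed);

  Nucleus stn, gpe, gpi;
  stn.init(n, as<NumericVector>(cfg["stn_params"]), rng, 5.0);
  gpe.init(n, as<NumericVector>(cfg["gpe_params"]), rng, 5.0);
  gpi.init(n, as<NumericVector>(cfg["gpi_params"]), rng, 5.0);

  // optional explicit initial state (used by equivalence tests)
  if (cfg.containsElementNamed("stn_v0") && !Rf_isNull(cfg["stn_v0"])) {
    NumericVector v0 = cfg["stn_v0"], u0 = cfg["stn_u0"];
    for (int i = 0; i < n; ++i) { stn.v[i] = v0[i]; stn.u[i] = u0[i]; }
  }

  // projection gains (magnitudes, pA per unit synaptic activation)
  const double g_gpe_stn = as<double>(cfg["g_gpe_stn"]);   // inhibitory
  const double g_stn_gpe = as<double>(cfg["g_stn_gpe"]);   // excitatory
  const double g_d2_gpe  = as<double>(cfg["g_d2_gpe"]);    // inhibitory
  const double g_d1_gpi  = as<double>(cfg["g_d1_gpi"]);    // inhibitory
  const double g_stn_gpi = as<double>(cfg["g_stn_gpi"]);   // excitatory
  const double g_lat_stn = as<double>(cfg["g_lat_stn"]);   // excitatory, DA-scaled upstream
  const double g_lat_gpe = as<double>(cfg["g_lat_gpe"]);   // inhibitory, DA-scaled upstream

  const double dec_exc = std::exp(-dt / as<double>(cfg["tau_exc"]));
  const double dec_inh = std::exp(-dt / as<double>(cfg["tau_inh"]));
  const double dec_str = std::exp(-dt / as<double>(cfg["tau_str"]));

  // striatal Poisson drive: per-deck rates (Hz) mapped through the quadrant
  // index of each lattice position (0..3)
  NumericVector rate_d1 = cfg["rate_d1"], rate_d2 = cfg["rate_d2"];
  IntegerVector quad = cfg["quadrant"];  // length n, values 0..3
  double p_d1[4], p_d2[4];
  for (int q = 0; q < 4; ++q) {
    p_d1[q] = rate_d1[q] * dt / 1000.0;
    p_d2[q] = rate_d2[q] * dt / 1000.0;
    if (p_d1[q] >= 1.0 || p_d2[q] >= 1.0)
      stop("Poisson rate * dt >= 1; dt too coarse for the requested rate");
  }
  int nq[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) nq[quad[i]]++;

  // DBS: precomputed spatial profile (pA at pulse peak), pulse timing
  NumericVector dbs_profile = cfg["dbs_profile"];  // length n (may be zeros)
  const double dbs_period = as<double>(cfg["dbs_period"]);  // ms
  const double dbs_pw = as<double>(cfg["dbs_phase_width"]); // ms
  bool dbs_any = false;
  for (int i = 0; i < n; ++i)
    if (dbs_profile[i] != 0.0) { dbs_any = true; break; }

  // thalamic race
  const bool do_race = as<bool>(cfg["race"]);
  const double race_drive = as<double>(cfg["race_drive"]);
  const double race_gain = as<double>(cfg["race_gain"]);
  const double race_leak = as<double>(cfg["race_leak"]);
  const double race_noise = as<double>(cfg["race_noise"]);
  const double race_threshold = as<double>(cfg["race_threshold"]);
  const double race_onset = as<double>(cfg["race_onset"]);
  const double tau_rate = as<double>(cfg["tau_rate"]);
  const double dec_rate = std::exp(-dt / tau_rate);
  const double sqdt = std::sqrt(dt);

  const bool rec_stn = as<bool>(cfg["record_stn"]);
  const bool rec_gpe = as<bool>(cfg["record_gpe"]);
  const bool rec_gpi = as<bool>(cfg["record_gpi"]);
  const bool rec_acc = as<bool>(cfg["record_acc"]);

  std::vector<int> stn_id, gpe_id, gpi_id;
  std::vector<double> stn_t, gpe_t, gpi_t;

  std::vector<double> s_stn(n, 0.0), s_gpe(n, 0.0), s_d1(n, 0.0), s_d2(n, 0.0);
  std::vector<double> lat_stn(n, 0.0), lat_gpe(n, 0.0);
  std::vector<double> I_stn(n), I_gpe(n), I_gpi(n);

  double rq[4] = {0, 0, 0, 0};  // smoothed GPi quadrant rates (Hz)
  double acc[4] = {0, 0, 0, 0};
  NumericMatrix acc_trace(rec_acc ? nsteps : 0, 4);

  long stn_spk_total = 0, gpe_spk_total = 0, gpi_spk_total = 0;
  std::vector<long> gpi_quad_count(4, 0), stn_quad_count(4, 0);

  int selected = -1;
  bool timeout = false;
  double decision_t = NA_REAL;
  int steps_run = nsteps;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // 1. synaptic filters: decay, then add last step's spikes / fresh
    //    striatal Poisson events
    for (int i = 0; i < n; ++i) {
      s_stn[i] = s_stn[i] * dec_exc + stn.spike[i];
      s_gpe[i] = s_gpe[i] * dec_inh + gpe.spike[i];
      int q = quad[i];
      double sp1 = (rng.unif() < p_d1[q]) ? 1.0 : 0.0;
      double sp2 = (rng.unif() < p_d2[q]) ? 1.0 : 0.0;
      s_d1[i] = s_d1[i] * dec_str + sp1;
      s_d2[i] = s_d2[i] * dec_str + sp2;
    }

    // 2. lateral kernels within STN and GPe
    if (g_lat_stn != 0.0) neighbour_sum(s_stn, nr, nc, lat_stn);
    if (g_lat_gpe != 0.0) neighbour_sum(s_gpe, nr, nc, lat_gpe);

    // 3. input currents (anatomy: GPe->STN inhibitory, STN->GPe/GPi
    //    excitatory, D1->GPi and D2->GPe inhibitory GABAergic MSNs)
    const double pol = dbs_any ? dbs_polarity(t, dbs_period, dbs_pw) : 0.0;
    for (int i = 0; i < n; ++i) {
      double idbs = (pol != 0.0) ? pol * dbs_profile[i] : 0.0;
      I_stn[i] = stn.bias - g_gpe_stn * s_gpe[i] + g_lat_stn * lat_stn[i] + idbs;
      I_gpe[i] = gpe.bias + g_stn_gpe * s_stn[i] - g_d2_gpe * s_d2[i]
                 - g_lat_gpe * lat_gpe[i];
      I_gpi[i] = gpi.bias + g_stn_gpi * s_stn[i] - g_d1_gpi * s_d1[i];
    }

    // 4. membrane updates
    stn.step(I_stn, dt);
    gpe.step(I_gpe, dt);
    gpi.step(I_gpi, dt);

    int gq[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (stn.spike[i]) {
        ++stn_spk_total;
        ++stn_quad_count[quad[i]];
        if (rec_stn) { stn_id.push_back(i + 1); stn_t.push_back(t + dt); }
      }
      if (gpe.spike[i]) {
        ++gpe_spk_total;
        if (rec_gpe) { gpe_id.push_back(i + 1); gpe_t.push_back(t + dt); }
      }
      if (gpi.spike[i]) {
        ++gpi_spk_total;
        gq[quad[i]]++;
        ++gpi_quad_count[quad[i]];
        if (rec_gpi) { gpi_id.push_back(i + 1); gpi_t.push_back(t + dt); }
      }
    }

    // 5. smoothed GPi quadrant rates (Hz per neuron)
    for (int q = 0; q < 4; ++q) {
      double inst = (nq[q] > 0) ? gq[q] * 1000.0 / (nq[q] * dt) : 0.0;
      rq[q] = rq[q] * dec_rate + (1.0 - dec_rate) * inst;
    }

    // 6. thalamic race: leaky accumulators, GPi inhibits its deck's unit.
    //    The race opens after a settle period so decisions read the
    //    steady-state pallidal output, not the startup transient.
    if ((do_race || rec_acc) && t >= race_onset) {
      int crossers[4], ncross = 0;
      for (int q = 0; q < 4; ++q) {
        acc[q] += dt * (race_drive - race_gain * rq[q] - race_leak * acc[q])
                  + race_noise * sqdt * rng.norm();
        if (acc[q] < 0.0) acc[q] = 0.0;
        if (rec_acc) acc_trace(step, q) = acc[q];
        if (do_race && acc[q] >= race_threshold) crossers[ncross++] = q;
      }
      if (ncross == 1) {
        selected = crossers[0];
      } else if (ncross > 1) {
        selected = crossers[(int)(rng.unif() * ncross) % ncross];
      }
      if (selected >= 0) {
        decision_t = t + dt;
        steps_run = step + 1;
        break;
      }
    }

    // instability guard: diverging membrane potential means dt too coarse
    if (!std::isfinite(stn.v[0]) || !std::isfinite(gpe.v[0]) ||
        !std::isfinite(gpi.v[0])) {
      stop("non-finite membrane state at t=%.2f ms (dt=%.3f); reduce dt", t, dt);
    }
  }

  if (do_race && selected < 0) {
    // timeout: fall back to the largest accumulator
    timeout = true;
    int best = 0;
    for (int q = 1; q < 4; ++q)
      if (acc[q] > acc[best]) best = q;
    selected = best;
    decision_t = steps_run * dt;
  }

  double dur_s = steps_run * dt / 1000.0;
  NumericVector quad_rate_gpi(4), quad_rate_stn(4);
  for (int q = 0; q < 4; ++q) {
    quad_rate_gpi[q] = (nq[q] > 0) ? gpi_quad_count[q] / (nq[q] * dur_s) : 0.0;
    quad_rate_stn[q] = (nq[q] > 0) ? stn_quad_count[q] / (nq[q] * dur_s) : 0.0;
  }

  List out = List::create(
      _["selected"] = selected + 1,
      _["timeout"] = timeout,
      _["decision_time"] = decision_t,
      _["steps_run"] = steps_run,
      _["duration_ms"] = steps_run * dt,
      _["acc"] = NumericVector(acc, acc + 4),
      _["spike_counts"] = NumericVector::create(
          _["STN"] = (double)stn_spk_total, _["GPe"] = (double)gpe_spk_total,
          _["GPi"] = (double)gpi_spk_total),
      _["gpi_quadrant_rates"] = quad_rate_gpi,
      _["stn_quadrant_rates"] = quad_rate_stn,
      _["stn_v"] = NumericVector(stn.v.begin(), stn.v.end()),
      _["stn_u"] = NumericVector(stn.u.begin(), stn.u.end()));

  if (rec_stn)
    out["stn_spikes"] = DataFrame::create(_["neuron"] = wrap(stn_id),
                                          _["time_ms"] = wrap(stn_t));
  if (rec_gpe)
    out["gpe_spikes"] = DataFrame::create(_["neuron"] = wrap(gpe_id),
                                          _["time_ms"] = wrap(gpe_t));
  if (rec_gpi)
    out["gpi_spikes"] = DataFrame::create(_["neuron"] = wrap(gpi_id),
                                          _["time_ms"] = wrap(gpi_t));
  if (rec_acc) out["acc_trace"] = acc_trace;

  return out;
}

// Single lattice Euler step used by equivalence tests against the R
// implementation (same arithmetic as Nucleus::step, no RNG involved).
// [[Rcpp::export(name = ".izh_step_cpp")]]
List izh_step_cpp(NumericVector v, NumericVector u, double a, double b,
                  double c, double d, double vpeak, NumericVector I,
                  double dt) {
  int n = v.size();
  NumericVector vn(n), un(n);
  LogicalVector sp(n);
  for (int i = 0; i < n; ++i) {
    double vv = v[i] + dt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I[i]);
    double uu = u[i] + dt * (a * (b * v[i] - u[i]));
    if (vv >= vpeak) {
      sp[i] = true;
      vv = c;
      uu += d;
    } else {
      sp[i] = false;
    }
    vn[i] = vv;
    un[i] = uu;
  }
  return List::create(_["v"] = vn, _["u"] = un, _["spiked"] = sp);
}
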