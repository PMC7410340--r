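#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xoshiro256+ with splitmix64 seeding: fast deterministic noise source
// (~1e8 normal draws per simulated second at full network size).
struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit Rng(uint64_t seed) : spare(0), has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() { // Marsaglia polar method (no trig calls)
    if (has_spare) { has_spare = false; return spare; }
    double x, y, s;
    do {
      x = 2.0 * unif() - 1.0;
      y = 2.0 * unif() - 1.0;
      s = x * x + y * y;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = y * m;
    has_spare = true;
    return x * m;
  }
};

struct Sched {
  const double *start, *end, *amp;
  int n, idx;
  Sched(const NumericMatrix &m)
    : start(m.nrow() ? &m(0, 0) : nullptr),
      end(m.nrow() ? &m(0, 1) : nullptr),
      amp(m.nrow() ? &m(0, 2) : nullptr), n(m.nrow()), idx(0) {}
  double at(double t) {
    while (idx < n && t >= end[idx]) ++idx;
    if (idx < n && t >= start[idx]) return amp[idx];
    return 0.0;
  }
};

// Square-wave tone gate per unit from sorted non-overlapping intervals.
struct Gate {
  const double *on, *off;
  int n, idx;
  Gate(const NumericMatrix &m)
    : on(m.nrow() ? &m(0, 0) : nullptr),
      off(m.nrow() ? &m(0, 1) : nullptr), n(m.nrow()), idx(0) {}
  double at(double t) {
    while (idx < n && t >= off[idx]) ++idx;
    return (idx < n && t >= on[idx]) ? 1.0 : 0.0;
  }
};

enum Cls { C_EE = 0, C_EP, C_ES, C_PE, C_PP, C_PS, C_SE, N_CLS };

// [[Rcpp::export(name = ".spiking_integrate_cpp")]]
List spiking_integrate_cpp(List net, List pars, List tone_intervals,
                           NumericMatrix opto_pv, NumericMatrix opto_sst,
                           double t_end, double dt, double record_dt,
                           double rng_seed, bool return_spikes) {
  const int n_units = as<int>(net["n_units"]);
  const int ne = as<int>(net["n_e"]), np = as<int>(net["n_p"]),
            ns = as<int>(net["n_s"]);
  const int per_unit = ne + np + ns, N = n_units * per_unit;
  IntegerVector out_ptr = net["out_ptr"], out_tgt = net["out_tgt"],
                out_cls = net["out_cls"];
  NumericVector inc = net["increment"], tau_syn = net["tau_syn"];

  // population parameter vectors ordered (Exc, PV, SST)
  NumericVector Cm = pars["C_m"], EL = pars["E_L"], gL = pars["g_L"],
                DT = pars["Delta_T"], VT = pars["V_T"], Vre = pars["V_reset"],
                Ib = pars["I_baseline"], vcut = pars["spike_cutoff"];
  const double aw = pars["a_w"], tauw = pars["tau_w"],
               bw_pA = 1000.0 * as<double>(pars["b_w"]);
  const double refr_ms = pars["refractory"];
  const double E_exc = pars["E_exc"], E_inh = pars["E_inh"];
  const double a_pv = pars["a_pv"], b_fac = pars["b_fac"];
  const double kappa = pars["kappa"], gsd = pars["g_sd"];
  const double sigma = pars["noise_sigma"], q = pars["q"],
               spread = pars["lateral_spread"];
  const double tau_I = pars["tau_I"], tau_dfast = pars["tau_d_fast"],
               tau_d1 = pars["tau_d1"], tau_d2 = pars["tau_d2"],
               tau_f1 = pars["tau_f1"], tau_f2 = pars["tau_f2"];
  const double Cm_d = pars["C_m_dend"], gL_d = pars["g_L_dend"];

  const int refr_steps = (int)std::floor(refr_ms / dt + 0.5);
  const long nstep = (long)std::floor(t_end / dt + 0.5);
  const int nrec = (int)std::ceil(t_end / record_dt);

  std::vector<double> V(N), w(N, 0.0), VD(N, 0.0);
  std::vector<int> refr(N, 0), pop(N), unit(N);
  for (int i = 0; i < N; ++i) {
    int k = i / per_unit, j = i % per_unit;
    unit[i] = k;
    pop[i] = (j < ne) ? 0 : (j < ne + np ? 1 : 2);
    V[i] = EL[pop[i]];
    VD[i] = EL[0];
  }
  std::vector<std::vector<double>> g(N_CLS, std::vector<double>(N, 0.0));
  double dec[N_CLS];
  for (int c = 0; c < N_CLS; ++c) dec[c] = std::exp(-dt / tau_syn[c]);

  std::vector<Gate> gates;
  for (int k = 0; k < n_units; ++k)
    gates.push_back(Gate(as<NumericMatrix>(tone_intervals[k])));
  Sched pv(opto_pv), sst(opto_sst);

  // per-unit slow variables (thalamic profile, PV->Exc depression, dendritic
  // facilitation), all driven by the unit's own tone gate
  std::vector<double> Ifast(n_units, 0.0), Dslow(n_units, 1.0),
      Dfast(n_units, 1.0), Dpv(n_units, 1.0), Ffac(n_units, 0.0),
      thal(n_units, 0.0), Tk(n_units, 0.0);

  Rng rng((uint64_t)rng_seed);
  const double nse = sigma * std::sqrt(2.0 * dt * gL[0] / Cm[0]);
  const double nsp = sigma * std::sqrt(2.0 * dt * gL[1] / Cm[1]);
  const double nss = sigma * std::sqrt(2.0 * dt * gL[2] / Cm[2]);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  IntegerMatrix counts(nrec, n_units * 3);
  // per unit: mean recurrent exc syn current, PV-soma inh, SST-dend inh (nA,
  // magnitudes), thalamic drive (nA), Exc rate bookkeeping done in R
  NumericMatrix cur(nrec, n_units * 4);
  IntegerVector cur_nacc(nrec, 0);

  for (long step = 0; step < nstep; ++step) {
    const double t = step * dt;
    const int bin = std::min(nrec - 1, (int)(t / record_dt));
    const double opv = pv.at(t), osst = sst.at(t);

    for (int k = 0; k < n_units; ++k) {
      double sq = gates[k].at(t);
      Ifast[k] += dt * (-Ifast[k] + sq) / tau_I;
      Dslow[k] += dt * ((1.0 - Dslow[k]) / tau_d1 - Dslow[k] * sq / tau_d2);
      Dfast[k] += dt * (1.0 - Dfast[k] - sq) / tau_dfast;
      Dpv[k] += dt * ((1.0 - Dpv[k]) / tau_d1 - Dpv[k] * sq / tau_d2);
      Ffac[k] += dt * (-Ffac[k] / tau_f1 + sq / tau_f2);
      Tk[k] = Ifast[k] * Dslow[k] * Dfast[k];
    }
    for (int k = 0; k < n_units; ++k) {
      double lat = 0.0;
      if (k > 0) lat += Tk[k - 1];
      if (k < n_units - 1) lat += Tk[k + 1];
      thal[k] = q * (Tk[k] + spread * lat);
    }

    double acc_exc[8] = {0}, acc_ip[8] = {0}, acc_id[8] = {0};

    for (int i = 0; i < N; ++i) {
      const int P = pop[i], k = unit[i];
      double Vi = V[i];

      if (P == 0) { // two-compartment Exc: dendrite first (no noise there)
        double VDi = VD[i];
        double dVD = (-gL_d * (VDi - EL[0]) - gsd * (VDi - Vi) / kappa -
                      g[C_ES][i] * (VDi - E_inh)) / Cm_d;
        VD[i] = VDi + dt * dVD;
      }

      if (refr[i] > 0) { --refr[i]; V[i] = Vre[P]; continue; }

      double Isyn_pA, Iext_nA;
      if (P == 0) {
        double iexc = -g[C_EE][i] * (Vi - E_exc);
        double iinh = -g[C_EP][i] * (a_pv * Dpv[k]) * (Vi - E_inh);
        double idend = -gsd * (1.0 + b_fac * Ffac[k]) * (Vi - VD[i]) / (1.0 - kappa);
        Isyn_pA = iexc + iinh + idend;
        Iext_nA = Ib[0] + thal[k];
        acc_exc[k] += iexc;
        acc_ip[k] += g[C_EP][i] * (a_pv * Dpv[k]) * (Vi - E_inh);
        acc_id[k] += g[C_ES][i] * (VD[i] - E_inh);
      } else if (P == 1) {
        Isyn_pA = -g[C_PE][i] * (Vi - E_exc) - (g[C_PP][i] + g[C_PS][i]) * (Vi - E_inh);
        Iext_nA = Ib[1] + thal[k] + opv;
      } else {
        Isyn_pA = -g[C_SE][i] * (Vi - E_exc);
        Iext_nA = Ib[2] + osst;
      }

      double ex = (Vi - VT[P]) / DT[P];
      if (ex > 30.0) ex = 30.0;
      // the spike-initiation term is < 1e-4 pA more than ~10 widths below
      // threshold; skipping the exp there roughly halves the step cost
      double spike_term = (ex > -10.0) ? gL[P] * DT[P] * std::exp(ex) : 0.0;
      double dV = (-gL[P] * (Vi - EL[P]) + spike_term -
                   w[i] + Isyn_pA + 1000.0 * Iext_nA) / Cm[P];
      double nz = (P == 0 ? nse : (P == 1 ? nsp : nss)) * rng.norm();
      Vi += dt * dV + nz;
      w[i] += dt * (aw * (Vi - EL[P]) - w[i]) / tauw;

      if (Vi >= vcut[P]) {
        if (return_spikes) { sp_t.push_back(t); sp_id.push_back(i + 1); }
        ++counts(bin, k * 3 + P);
        Vi = Vre[P];
        w[i] += bw_pA;
        refr[i] = refr_steps;
        for (int e = out_ptr[i]; e < out_ptr[i + 1]; ++e)
          g[out_cls[e]][out_tgt[e]] += inc[out_cls[e]];
      }
      V[i] = Vi;
      if (!std::isfinite(Vi))
        stop("spiking integration diverged: neuron %d at t = %f ms", i + 1, t);
    }

    // decay only the population slice each conductance class lives on
    for (int c = 0; c < N_CLS; ++c) {
      double d = dec[c];
      double *gc = g[c].data();
      int off = (c <= C_ES) ? 0 : (c <= C_PS ? ne : ne + np);
      int len = (c <= C_ES) ? ne : (c <= C_PS ? np : ns);
      for (int k = 0; k < n_units; ++k) {
        double *p0 = gc + k * per_unit + off;
        for (int i = 0; i < len; ++i) p0[i] *= d;
      }
    }

    for (int k = 0; k < n_units; ++k) {
      cur(bin, k * 4 + 0) += acc_exc[k] / (1000.0 * ne);
      cur(bin, k * 4 + 1) += acc_ip[k] / (1000.0 * ne);
      cur(bin, k * 4 + 2) += acc_id[k] / (1000.0 * ne);
      cur(bin, k * 4 + 3) += thal[k];
    }
    ++cur_nacc[bin];
  }

  for (int b = 0; b < nrec; ++b)
    if (cur_nacc[b] > 0)
      for (int j = 0; j < n_units * 4; ++j) cur(b, j) /= cur_nacc[b];

  NumericVector rec_time(nrec);
  for (int b = 0; b < nrec; ++b) rec_time[b] = (b + 0.5) * record_dt;

  return List::create(_["spike_t"] = wrap(sp_t), _["spike_id"] = wrap(sp_id),
                      _["counts"] = counts, _["currents"] = cur,
                      _["time"] = rec_time);
}
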