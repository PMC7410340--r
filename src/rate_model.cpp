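#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Threshold-linear gain: 0 below threshold, slope r, saturates at 1.
static inline double fthr(double x, double r) {
  if (x <= 0.0) return 0.0;
  double y = r * x;
  return (y > 1.0) ? 1.0 : y;
}

// Piecewise-constant schedule lookup over sorted, non-overlapping [start,end)
// windows; evaluation times are non-decreasing so a moving cursor suffices.
struct Schedule {
  const double *start, *end, *amp;
  int n, idx;
  Schedule(const NumericMatrix &m)
    : start(m.nrow() ? &m(0, 0) : nullptr),
      end(m.nrow() ? &m(0, 1) : nullptr),
      amp(m.nrow() ? &m(0, 2) : nullptr),
      n(m.nrow()), idx(0) {}
  double at(double t) {
    while (idx < n && t >= end[idx]) ++idx;
    if (idx < n && t >= start[idx]) return amp[idx];
    return 0.0;
  }
};

struct RatePars {
  int n;           // 1 or 3 units
  double W[9];     // row-major: ee,ep,es, pe,pp,ps, se,sp,ss
  double uth, pth, sth, r;
  double tau_u, tau_p, tau_s;
  double q, tau_q, tau_d1, tau_d2, g0;
  double a_dep, b_fac, alpha;
  double wee_l, wpe_l, wse_l;
  bool proxy;      // F = 1 - g, D = g instead of the integrated states
};

// State layout: u[n], p[n], s[n], g[n], F[n], D[n]
static void rate_rhs(const RatePars &P, const double *y, const double *inp,
                     double opv, double osst, double *dy) {
  const int n = P.n;
  const double *u = y, *p = y + n, *s = y + 2 * n, *g = y + 3 * n,
               *Fs = y + 4 * n, *Ds = y + 5 * n;
  double *du = dy, *dp = dy + n, *ds = dy + 2 * n, *dg = dy + 3 * n,
         *dF = dy + 4 * n, *dD = dy + 5 * n;

  // thalamic drives with cross-unit spread (single unit: no mixing)
  double I[3] = {0, 0, 0};
  if (n == 1) {
    I[0] = g[0] * inp[0];
  } else {
    I[0] = g[0] * inp[0] + P.alpha * g[1] * inp[1];
    I[1] = P.alpha * (g[0] * inp[0] + g[2] * inp[2]) + g[1] * inp[1];
    I[2] = g[2] * inp[2] + P.alpha * g[1] * inp[1];
  }

  for (int i = 0; i < n; ++i) {
    double Fi = P.proxy ? (1.0 - g[i]) : Fs[i];
    double Di = P.proxy ? g[i] : Ds[i];
    double wep_eff = (n == 3) ? (P.W[1] - P.a_dep * (1.0 - Di)) : P.W[1];

    double J1 = P.q * I[i], J2 = P.q * I[i], J3 = 0.0;
    if (n == 3) {
      if (i == 1) { // center unit: mean of the two edges
        J1 += -P.b_fac * Fi * (s[0] + s[2]) + P.wee_l * (u[0] + u[2]) / 2.0;
        J2 += P.wpe_l * (u[0] + u[2]) / 2.0;
        J3 += P.wse_l * (u[0] + u[2]) / 2.0;
      } else {      // edge units receive from the center only
        J1 += -P.b_fac * Fi * s[1] + P.wee_l * u[1];
        J2 += P.wpe_l * u[1];
        J3 += P.wse_l * u[1];
      }
    }

    double au = P.W[0] * u[i] - wep_eff * p[i] - P.W[2] * s[i] + J1 - P.uth;
    double ap = P.W[3] * u[i] - P.W[4] * p[i] - P.W[5] * s[i] + opv + J2 - P.pth;
    double as = P.W[6] * u[i] - P.W[7] * p[i] - P.W[8] * s[i] + osst + J3 - P.sth;

    du[i] = (-u[i] + fthr(au, P.r)) / P.tau_u;
    dp[i] = (-p[i] + fthr(ap, P.r)) / P.tau_p;
    ds[i] = (-s[i] + fthr(as, P.r)) / P.tau_s;
    dg[i] = (P.g0 - g[i]) / P.tau_d1 - g[i] * inp[i] / P.tau_d2;
    dF[i] = -Fs[i] / P.tau_d1 + inp[i] / P.tau_d2;
    dD[i] = (1.0 - Ds[i]) / P.tau_d1 - Ds[i] * inp[i] / P.tau_d2;
  }
}

// [[Rcpp::export(name = ".rate_integrate_cpp")]]
List rate_integrate_cpp(List pars, List tone_onsets, List tone_amps,
                        NumericMatrix opto_pv, NumericMatrix opto_sst,
                        double t_end, double dt, int record_every) {
  RatePars P;
  P.n = as<int>(pars["n_units"]);
  NumericVector W = pars["W"];
  for (int i = 0; i < 9; ++i) P.W[i] = W[i];
  P.uth = pars["u_th"]; P.pth = pars["p_th"]; P.sth = pars["s_th"];
  P.r = pars["r"];
  P.tau_u = pars["tau_u"]; P.tau_p = pars["tau_p"]; P.tau_s = pars["tau_s"];
  P.q = pars["q"]; P.tau_q = pars["tau_q"];
  P.tau_d1 = pars["tau_d1"]; P.tau_d2 = pars["tau_d2"]; P.g0 = pars["g0"];
  P.a_dep = pars["a_dep"]; P.b_fac = pars["b_fac"]; P.alpha = pars["alpha"];
  P.wee_l = pars["w_ee_lat"]; P.wpe_l = pars["w_pe_lat"]; P.wse_l = pars["w_se_lat"];
  P.proxy = as<bool>(pars["use_proxy"]);
  const int n = P.n, nv = 6 * n;

  std::vector<std::vector<double>> ons(n), amps(n);
  std::vector<size_t> next_tone(n, 0);
  for (int k = 0; k < n; ++k) {
    NumericVector o = tone_onsets[k], a = tone_amps[k];
    ons[k] = std::vector<double>(o.begin(), o.end());
    amps[k] = std::vector<double>(a.begin(), a.end());
  }

  Schedule pv(opto_pv), sst(opto_sst);
  // opto values can be looked up at t, t+dt/2, t+dt within a step; keep three
  // cursors so each sequence of lookups stays non-decreasing
  Schedule pv2(opto_pv), sst2(opto_sst), pv3(opto_pv), sst3(opto_sst);

  long nstep = (long)std::floor(t_end / dt + 0.5);
  long nrec = nstep / record_every + 1;
  // columns per unit: u p s g F D exc inh thal ; plus leading time column
  NumericMatrix out(nrec, 1 + 9 * n);

  std::vector<double> y(nv, 0.0), k1(nv), k2(nv), k3(nv), k4(nv), yt(nv);
  for (int k = 0; k < n; ++k) { y[3 * n + k] = P.g0; y[5 * n + k] = 1.0; }
  std::vector<double> i0(n, 0.0), ih(n), ifull(n);
  const double eh2 = std::exp(-0.5 * dt / P.tau_q), eh = eh2 * eh2;

  long irec = 0;
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    // tone onsets aligned to the grid: apply jumps at step start
    for (int k = 0; k < n; ++k)
      while (next_tone[k] < ons[k].size() && ons[k][next_tone[k]] <= t + 1e-9) {
        i0[k] += amps[k][next_tone[k]];
        ++next_tone[k];
      }

    if (step % record_every == 0) {
      out(irec, 0) = t;
      const double *u = y.data(), *p = u + n, *s = p + n, *g = s + n,
                   *Fs = g + n, *Ds = Fs + n;
      double opv0 = pv.at(t), osst0 = sst.at(t);
      (void)osst0;
      double I[3] = {0, 0, 0};
      if (n == 1) I[0] = g[0] * i0[0];
      else {
        I[0] = g[0] * i0[0] + P.alpha * g[1] * i0[1];
        I[1] = P.alpha * (g[0] * i0[0] + g[2] * i0[2]) + g[1] * i0[1];
        I[2] = g[2] * i0[2] + P.alpha * g[1] * i0[1];
      }
      for (int k = 0; k < n; ++k) {
        double Fi = P.proxy ? (1.0 - g[k]) : Fs[k];
        double Di = P.proxy ? g[k] : Ds[k];
        double wep_eff = (n == 3) ? (P.W[1] - P.a_dep * (1.0 - Di)) : P.W[1];
        double exc = P.W[0] * u[k] + P.q * I[k];
        double inh = wep_eff * p[k] + P.W[2] * s[k];
        if (n == 3) {
          if (k == 1) {
            exc += P.wee_l * (u[0] + u[2]) / 2.0;
            inh += P.b_fac * Fi * (s[0] + s[2]);
          } else {
            exc += P.wee_l * u[1];
            inh += P.b_fac * Fi * s[1];
          }
        }
        out(irec, 1 + 9 * k + 0) = u[k];
        out(irec, 1 + 9 * k + 1) = p[k];
        out(irec, 1 + 9 * k + 2) = s[k];
        out(irec, 1 + 9 * k + 3) = g[k];
        out(irec, 1 + 9 * k + 4) = Fi;
        out(irec, 1 + 9 * k + 5) = Di;
        out(irec, 1 + 9 * k + 6) = exc;
        out(irec, 1 + 9 * k + 7) = inh;
        out(irec, 1 + 9 * k + 8) = P.q * I[k];
      }
      (void)opv0;
      ++irec;
    }
    if (step == nstep) break;

    // RK4 with the exogenous input advanced analytically (pure decay)
    double tm = t + 0.5 * dt, tf = t + dt;
    for (int k = 0; k < n; ++k) { ih[k] = i0[k] * eh2; ifull[k] = i0[k] * eh; }
    rate_rhs(P, y.data(), i0.data(), pv.at(t), sst.at(t), k1.data());
    for (int j = 0; j < nv; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    rate_rhs(P, yt.data(), ih.data(), pv2.at(tm), sst2.at(tm), k2.data());
    for (int j = 0; j < nv; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    rate_rhs(P, yt.data(), ih.data(), pv2.at(tm), sst2.at(tm), k3.data());
    for (int j = 0; j < nv; ++j) yt[j] = y[j] + dt * k3[j];
    rate_rhs(P, yt.data(), ifull.data(), pv3.at(tf), sst3.at(tf), k4.data());
    for (int j = 0; j < nv; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    for (int k = 0; k < n; ++k) i0[k] *= eh;

    for (int j = 0; j < nv; ++j)
      if (!std::isfinite(y[j]))
        stop("rate integration diverged (non-finite state) at t = %f ms", t);
  }

  return List::create(_["traces"] = out, _["n_units"] = n);
}
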