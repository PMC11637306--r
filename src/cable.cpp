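// Implicit compartmental cable solver with Hodgkin-Huxley Na/K currents,
// an optional compensatory K conductance, a slow cumulative K inactivation
// gate, and a GHK calcium channel mixture (P/Q, N, R subtypes).
//
// Units at this level are absolute circuit units: mV, ms, nF, uS, nA, MOhm
// (uS*mV = nA and nF*mV/ms = nA).
// Conversions from specific units (uF/cm2, mS/cm2, Ohm*cm) happen in R.
#include <Rcpp.h>
using namespace Rcpp;

static const double FARADAY = 96485.332;   // C/mol
static const double RGAS    = 8.314462;    // J/(mol K)

// x/(1 - exp(-x)) with removable singularity at 0
static inline double xdivexpm1(double x) {
  if (std::fabs(x) < 1e-9) return 1.0 + 0.5 * x;
  return x / (-std::expm1(-x));
}

// linear/exponential HH rate helper: a*(v-th)/(1-exp(-(v-th)/q))
static inline double vtrap(double a, double v, double th, double q) {
  double x = (v - th) / q;
  return a * q * xdivexpm1(x);
}

// Canonical squid-axon rate equations, uniformly shifted by vs (mV) and
// scaled by rs.  gate: 0=m, 1=h, 2=n.
static void hh_rates_c(double v, int gate, double vs, double rs,
                       double &alpha, double &beta) {
  double u = v - vs;
  switch (gate) {
  case 0:
    alpha = vtrap(0.1, u, -40.0, 10.0);
    beta  = 4.0 * std::exp(-(u + 65.0) / 18.0);
    break;
  case 1:
    alpha = 0.07 * std::exp(-(u + 65.0) / 20.0);
    beta  = 1.0 / (1.0 + std::exp(-(u + 35.0) / 10.0));
    break;
  case 2:
    alpha = vtrap(0.01, u, -55.0, 10.0);
    beta  = 0.125 * std::exp(-(u + 65.0) / 80.0);
    break;
  default:
    stop("unknown gate id");
  }
  alpha *= rs;
  beta  *= rs;
}

// GHK flux per unit permeability: mA/cm2 per (cm/s), concentrations in mM.
static inline double ghk_flux_c(double v, double z, double cin, double cout,
                                double TK) {
  double xi = z * FARADAY * v * 1e-3 / (RGAS * TK);
  double frac;  // (cin - cout*exp(-xi)) / (1 - exp(-xi)) handled stably
  if (std::fabs(xi) < 1e-9) {
    // series: (cin - cout(1-xi)) / xi -> limit handled as a whole below
    frac = (cin - cout) + 0.5 * xi * (cin + cout);
    return 96.485 * z * frac;
  }
  frac = (cin - cout * std::exp(-xi)) / (-std::expm1(-xi));
  return 96.485 * z * xi * frac;
}

// symmetric single-activation-gate rates for Ca subtypes
static inline void ca_gate_rates_c(double v, double vh, double k, double a,
                                   double tempfac, double &alpha,
                                   double &beta) {
  alpha = a * std::exp((v - vh) / (2.0 * k)) * tempfac;
  beta  = a * std::exp(-(v - vh) / (2.0 * k)) * tempfac;
}

// slow cumulative inactivation of the backbone K current
static inline void kslow_inf_tau(double v, double vh, double kk, double tau,
                                 double &sinf, double &stau) {
  sinf = 1.0 / (1.0 + std::exp((v - vh) / kk));
  stau = tau;
}

// [[Rcpp::export]]
List cpp_hh_rates(double v, int gate, double vshift, double rate_scale) {
  double a, b;
  hh_rates_c(v, gate, vshift, rate_scale, a, b);
  return List::create(_["alpha"] = a, _["beta"] = b);
}

// [[Rcpp::export]]
double cpp_ghk_flux(double v, double z, double cin, double cout, double TK) {
  return ghk_flux_c(v, z, cin, cout, TK);
}

// [[Rcpp::export]]
List cpp_ca_gate_rates(double v, double vh, double k, double a,
                       double tempfac) {
  double al, be;
  ca_gate_rates_c(v, vh, k, a, tempfac, al, be);
  return List::create(_["alpha"] = al, _["beta"] = be);
}

// Rush-Larsen exact exponential gate update
static inline double rl_update(double x, double alpha, double beta,
                               double dt) {
  double s = alpha + beta;
  if (s <= 0) return x;
  double xinf = alpha / s;
  return xinf + (x - xinf) * std::exp(-dt * s);
}

// [[Rcpp::export]]
List cpp_cable_run(List pars) {
  const int n = as<int>(pars["n"]);
  IntegerVector parent = pars["parent"];          // 0-based, -1 for root
  NumericVector c_nf = pars["c_nf"];
  NumericVector g_ax = pars["g_axial_us"];        // coupling to parent, uS
  NumericVector g_leak = pars["g_leak_us"];
  NumericVector e_leak_v = pars["e_leak"];        // per-compartment, mV
  NumericVector g_na = pars["g_na_us"];
  NumericVector g_k = pars["g_k_us"];
  NumericVector g_kc = pars["g_kc_us"];
  NumericVector pa_ca = pars["pa_ca"];            // 3 x n matrix flattened? no:
  // pa_ca is length 3*n: subtype-major blocks (PQ, N, R), P*area scaling so
  // that i_nA = pa * flux(mA/cm2 per cm/s)
  const double e_na = as<double>(pars["e_na"]);
  const double e_k = as<double>(pars["e_k"]);
  const double vshift = as<double>(pars["vshift"]);
  const double vshift_k = as<double>(pars["vshift_k"]);
  const double vshift_kc = as<double>(pars["vshift_kc"]);
  const double rs_kc = as<double>(pars["rate_scale_kc"]);
  const double rs_na = as<double>(pars["rate_scale_na"]);
  const double rs_h = as<double>(pars["rate_scale_h"]);
  const double rs_k = as<double>(pars["rate_scale_k"]);
  NumericVector ca_vh = pars["ca_vh"];            // length 3
  NumericVector ca_k = pars["ca_slope"];
  NumericVector ca_a = pars["ca_rate"];
  const double ca_tempfac = as<double>(pars["ca_tempfac"]);
  const double ca_in = as<double>(pars["ca_in"]);
  const double ca_out = as<double>(pars["ca_out"]);
  const double TK = as<double>(pars["temp_K"]);
  const bool kslow_on = as<bool>(pars["kslow_on"]);
  const double ks_vh = as<double>(pars["kslow_vh"]);
  const double ks_k = as<double>(pars["kslow_k"]);
  const double ks_tau = as<double>(pars["kslow_tau"]);

  const double dt = as<double>(pars["dt"]);
  const int nsteps = as<int>(pars["n_steps"]);
  const double v0 = as<double>(pars["v_init"]);
  const double theta = as<double>(pars["theta"]);  // 1 = backward Euler

  IntegerVector stim_sites = pars["stim_sites"];   // 0-based
  NumericMatrix stim_traces = pars["stim_traces"]; // nsteps x nsites (nA)

  const int vc_site = as<int>(pars["vc_site"]);    // -1 = none
  double vc_rs = as<double>(pars["vc_rs_mohm"]);
  NumericVector vc_cmd = pars["vc_command"];
  double g_clamp = 0.0;
  if (vc_site >= 0) {
    if (vc_rs < 1e-7) vc_rs = 1e-7;                // near-ideal clamp
    g_clamp = 1.0 / vc_rs;
  }

  IntegerVector rec_v = pars["record_v_idx"];      // 0-based
  IntegerVector rec_i = pars["record_i_idx"];
  IntegerVector rec_sp = pars["record_species"];   // flags: na,k,kc,ca,leak
  const int nrv = rec_v.size(), nri = rec_i.size();
  const bool r_na = rec_sp[0] > 0, r_k = rec_sp[1] > 0, r_kc = rec_sp[2] > 0,
             r_ca = rec_sp[3] > 0, r_lk = rec_sp[4] > 0;

  // state
  std::vector<double> v(n, v0), m(n), h(n), nn(n), p(n), s(n, 1.0);
  std::vector<double> apq(n), an(n), ar(n);
  {
    double a, b;
    for (int i = 0; i < n; ++i) {
      hh_rates_c(v0, 0, vshift, rs_na, a, b); m[i] = a / (a + b);
      hh_rates_c(v0, 1, vshift, rs_h, a, b); h[i] = a / (a + b);
      hh_rates_c(v0, 2, vshift + vshift_k, rs_k, a, b);  nn[i] = a / (a + b);
      hh_rates_c(v0, 2, vshift + vshift_kc, rs_kc, a, b);
      p[i] = a / (a + b);
      ca_gate_rates_c(v0, ca_vh[0], ca_k[0], ca_a[0], ca_tempfac, a, b);
      apq[i] = a / (a + b);
      ca_gate_rates_c(v0, ca_vh[1], ca_k[1], ca_a[1], ca_tempfac, a, b);
      an[i] = a / (a + b);
      ca_gate_rates_c(v0, ca_vh[2], ca_k[2], ca_a[2], ca_tempfac, a, b);
      ar[i] = a / (a + b);
      if (kslow_on) {
        double si, st;
        kslow_inf_tau(v0, ks_vh, ks_k, ks_tau, si, st);
        s[i] = si;
      }
    }
  }

  NumericMatrix V_out(nsteps, nrv);
  NumericMatrix Ina(nsteps, r_na ? nri : 0), Ik(nsteps, r_k ? nri : 0),
      Ikc(nsteps, r_kc ? nri : 0), Ica(nsteps, r_ca ? nri : 0),
      Ileak(nsteps, r_lk ? nri : 0);
  NumericVector Iclamp(vc_site >= 0 ? nsteps : 0);
  NumericVector tgrid(nsteps);

  std::vector<double> diag(n), rhs(n), offf(n), gtot(n), bion(n), ica(n);
  bool unstable = false;

  const double *pa0 = &pa_ca[0], *pa1 = &pa_ca[n], *pa2 = &pa_ca[2 * n];

  for (int step = 0; step < nsteps; ++step) {
    double t = (step + 1) * dt;
    tgrid[step] = t;

    // 1) gates: Rush-Larsen at frozen voltage
    double a, b;
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      bool active = (g_na[i] > 0) || (g_k[i] > 0) || (g_kc[i] > 0);
      if (active) {
        hh_rates_c(vi, 0, vshift, rs_na, a, b); m[i] = rl_update(m[i], a, b, dt);
        hh_rates_c(vi, 1, vshift, rs_h, a, b); h[i] = rl_update(h[i], a, b, dt);
        hh_rates_c(vi, 2, vshift + vshift_k, rs_k, a, b);  nn[i] = rl_update(nn[i], a, b, dt);
        if (g_kc[i] > 0) {
          hh_rates_c(vi, 2, vshift + vshift_kc, rs_kc, a, b); p[i] = rl_update(p[i], a, b, dt);
        }
        if (kslow_on) {
          double si, st;
          kslow_inf_tau(vi, ks_vh, ks_k, ks_tau, si, st);
          s[i] = si + (s[i] - si) * std::exp(-dt / st);
        }
      }
      if (pa0[i] > 0 || pa1[i] > 0 || pa2[i] > 0) {
        ca_gate_rates_c(vi, ca_vh[0], ca_k[0], ca_a[0], ca_tempfac, a, b);
        apq[i] = rl_update(apq[i], a, b, dt);
        ca_gate_rates_c(vi, ca_vh[1], ca_k[1], ca_a[1], ca_tempfac, a, b);
        an[i] = rl_update(an[i], a, b, dt);
        ca_gate_rates_c(vi, ca_vh[2], ca_k[2], ca_a[2], ca_tempfac, a, b);
        ar[i] = rl_update(ar[i], a, b, dt);
      }
    }

    // 2) conductances and non-linear (GHK) currents at current state
    double flux = 0.0;
    for (int i = 0; i < n; ++i) {
      double gna = g_na[i] * m[i] * m[i] * m[i] * h[i];
      double gk = g_k[i] * nn[i] * nn[i] * nn[i] * nn[i] * (kslow_on ? s[i] : 1.0);
      double gkc = g_kc[i] * p[i] * p[i] * p[i] * p[i];
      gtot[i] = gna + gk + gkc + g_leak[i];
      bion[i] = gna * e_na + (gk + gkc) * e_k + g_leak[i] * e_leak_v[i];
      double pa_eff = pa0[i] * apq[i] * apq[i] + pa1[i] * an[i] * an[i] +
                      pa2[i] * ar[i] * ar[i];
      if (pa_eff > 0) {
        flux = ghk_flux_c(v[i], 2.0, ca_in, ca_out, TK);
        ica[i] = pa_eff * flux;  // nA, inward negative
      } else {
        ica[i] = 0.0;
      }
    }

    // 3) assemble theta-method linear system
    for (int i = 0; i < n; ++i) {
      double cdt = c_nf[i] / dt;
      diag[i] = cdt + theta * gtot[i];
      rhs[i] = cdt * v[i] - (1.0 - theta) * gtot[i] * v[i] + bion[i] - ica[i];
      offf[i] = 0.0;
    }
    // axial coupling
    for (int i = 1; i < n; ++i) {
      int pi = parent[i];
      if (pi < 0) continue;
      double g = g_ax[i];
      double iax = g * (v[pi] - v[i]);  // current into i at old V
      diag[i] += theta * g;
      diag[pi] += theta * g;
      offf[i] = -theta * g;
      rhs[i] += (1.0 - theta) * iax;
      rhs[pi] -= (1.0 - theta) * iax;
    }
    // stimuli
    for (int sidx = 0; sidx < stim_sites.size(); ++sidx) {
      rhs[stim_sites[sidx]] += stim_traces(step, sidx);
    }
    // voltage clamp through series resistance
    if (vc_site >= 0) {
      diag[vc_site] += theta * g_clamp;
      rhs[vc_site] += g_clamp * vc_cmd[step] -
                      (1.0 - theta) * g_clamp * v[vc_site];
    }

    // 4) Hines tree solve (parent[i] < i guaranteed)
    for (int i = n - 1; i >= 1; --i) {
      int pi = parent[i];
      if (pi < 0) continue;
      double f = offf[i] / diag[i];
      diag[pi] -= f * offf[i];
      rhs[pi] -= f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int pi = parent[i];
      v[i] = (pi < 0) ? rhs[i] / diag[i]
                      : (rhs[i] - offf[i] * v[pi]) / diag[i];
    }

    // 5) record
    for (int r = 0; r < nrv; ++r) V_out(step, r) = v[rec_v[r]];
    for (int r = 0; r < nri; ++r) {
      int i = rec_i[r];
      double gna = g_na[i] * m[i] * m[i] * m[i] * h[i];
      double gk = g_k[i] * nn[i] * nn[i] * nn[i] * nn[i] * (kslow_on ? s[i] : 1.0);
      double gkc = g_kc[i] * p[i] * p[i] * p[i] * p[i];
      if (r_na) Ina(step, r) = gna * (v[i] - e_na);
      if (r_k) Ik(step, r) = gk * (v[i] - e_k);
      if (r_kc) Ikc(step, r) = gkc * (v[i] - e_k);
      if (r_ca) {
        double pa_eff = pa0[i] * apq[i] * apq[i] + pa1[i] * an[i] * an[i] +
                        pa2[i] * ar[i] * ar[i];
        Ica(step, r) = pa_eff > 0
                           ? pa_eff * ghk_flux_c(v[i], 2.0, ca_in, ca_out, TK)
                           : 0.0;
      }
      if (r_lk) Ileak(step, r) = g_leak[i] * (v[i] - e_leak_v[i]);
    }
    if (vc_site >= 0) Iclamp[step] = g_clamp * (vc_cmd[step] - v[vc_site]);

    for (int i = 0; i < n; ++i) {
      if (!R_finite(v[i]) || std::fabs(v[i]) > 150.0) unstable = true;
    }
  }

  return List::create(
      _["t"] = tgrid, _["v"] = V_out, _["i_na"] = Ina, _["i_k"] = Ik,
      _["i_k_comp"] = Ikc, _["i_ca"] = Ica, _["i_leak"] = Ileak,
      _["i_clamp"] = Iclamp, _["unstable"] = unstable);
}
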