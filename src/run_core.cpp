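#include <Rcpp.h>
#include <cmath>

// Compiled explicit-Euler stepper for the eight-pool nitrogen network.
// Mirrors the reference R implementation in ncycle_step() exactly:
// fluxes -> per-pool outflow limiting -> Euler update -> instantaneous
// Henry / Freundlich re-partitioning.

namespace {

struct Pars {
  // decay forcings: F1, F0, tau
  double com1, com0, comtau;
  double imp1, imp0, imptau;
  double hyd1, hyd0, hydtau;
  double mix1, mix0, mixtau;
  double lig_nox, lig_nhx;
  double alpha_a;
  double alpha_m, f_uma_ref, f_lma_ref, m_uma_ref, m_lma_ref;
  double D, eps;
  double erosion_rate;
  bool two_phase;
  double early_rate, late_rate, breakpoint, present_volume, thickness;
  double K, V_present, pal, p_ref, mm_n2;
  double Kf, nF, S_sed;
  double rock_u, rock_l;
  double vol_pct;
};

inline double forcing(double F1, double F0, double tau, double t) {
  return F0 + (F1 - F0) * std::exp(-t / tau);
}

// dissolved NHx from the monotone Freundlich mass balance (n != 1),
// bisection to 1e-13 relative
inline double freundlich_root(double mobile, double coef, double conc,
                              double inv_n) {
  double lo = 0.0, hi = mobile;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = mid + coef * std::pow(mid * conc, inv_n) - mobile;
    if (g > 0.0) hi = mid; else lo = mid;
    if ((hi - lo) <= 1e-13 * mobile) break;
  }
  return 0.5 * (lo + hi);
}

const int ATM = 0, ON2 = 1, NOX = 2, NHX = 3, SED = 4, CCR = 5,
          UMA = 6, LMA = 7;

void step(double* s, const Pars& P, double t, double dt) {
  const double atm = s[ATM];

  double comet = forcing(P.com1, P.com0, P.comtau, t);
  double imp_tot = forcing(P.imp1, P.imp0, P.imptau, t) * atm / P.pal;
  double imp_nox = (1.0 - P.alpha_a) * imp_tot;
  double imp_nhx = P.alpha_a * imp_tot;
  double lig_nox = P.lig_nox * atm / P.pal;
  double lig_nhx = P.lig_nhx * atm / P.pal;
  double rh = forcing(P.hyd1, P.hyd0, P.hydtau, t);
  double hyd_nox = rh * s[NOX];
  double hyd_n2 = rh * 1e-3 * s[ON2];
  double sub_uma = (1.0 - P.eps) * s[SED] / P.D;
  double sub_ccr = P.eps * s[SED] / P.D;
  double vol_km3 = P.two_phase
    ? P.early_rate * std::min(t, P.breakpoint) +
      P.late_rate * std::max(0.0, t - P.breakpoint)
    : P.present_volume * t / 4.5e9;
  // uniform crustal N: eroded volume fraction carries proportional N
  double ero = (vol_km3 > 0.0) ? s[CCR] * P.erosion_rate / P.thickness : 0.0;
  double deg_u = P.f_uma_ref * s[UMA] / P.m_uma_ref;
  double arc = P.alpha_m * deg_u;
  double morb = (1.0 - P.alpha_m) * deg_u;
  double hot = P.f_lma_ref * s[LMA] / P.m_lma_ref;
  double rm = forcing(P.mix1, P.mix0, P.mixtau, t);
  double exch = rm * (P.rock_u + P.rock_l);
  double mix_lu = exch * s[LMA] / P.rock_l;
  double mix_ul = exch * s[UMA] / P.rock_u;

  // outflow limiting: no pool may be drained below zero in one step
  double out;
  out = imp_nox + imp_nhx + lig_nox + lig_nhx;
  if (out * dt > s[ATM]) {
    double f = s[ATM] / (out * dt);
    imp_nox *= f; imp_nhx *= f; lig_nox *= f; lig_nhx *= f;
  }
  if (hyd_n2 * dt > s[ON2]) hyd_n2 = s[ON2] / dt;
  if (hyd_nox * dt > s[NOX]) hyd_nox = s[NOX] / dt;
  out = sub_uma + sub_ccr;
  if (out * dt > s[SED]) {
    double f = s[SED] / (out * dt);
    sub_uma *= f; sub_ccr *= f;
  }
  if (ero * dt > s[CCR]) ero = s[CCR] / dt;
  out = arc + morb + mix_ul;
  if (out * dt > s[UMA]) {
    double f = s[UMA] / (out * dt);
    arc *= f; morb *= f; mix_ul *= f;
  }
  out = hot + mix_lu;
  if (out * dt > s[LMA]) {
    double f = s[LMA] / (out * dt);
    hot *= f; mix_lu *= f;
  }

  double tot = 0.0;
  for (int j = 0; j < 8; ++j) tot += s[j];

  s[ATM] += (arc - imp_nox - imp_nhx - lig_nox - lig_nhx) * dt;
  s[ON2] += (-hyd_n2) * dt;
  s[NOX] += (imp_nox + lig_nox - hyd_nox) * dt;
  s[NHX] += (comet + imp_nhx + lig_nhx + hyd_nox + hyd_n2 + ero + morb + hot) * dt;
  s[SED] += (-sub_uma - sub_ccr) * dt;
  s[CCR] += (sub_ccr - ero) * dt;
  s[UMA] += (sub_uma + mix_lu - mix_ul - arc - morb) * dt;
  s[LMA] += (mix_ul - mix_lu - hot) * dt;

  for (int j = 0; j < 8; ++j) {
    if (s[j] < 0.0 && s[j] > -(1e-12 * tot + 1e-9))
      s[j] = 0.0;  // roundoff on a drained pool
    if (!R_FINITE(s[j]) || s[j] < 0.0)
      Rcpp::stop("non-finite or negative pool %d after step at t = %g", j + 1, t);
  }

  // instantaneous equilibria on the instantaneous ocean volume
  double V0 = P.V_present / (1.0 + P.vol_pct / 100.0);
  double V = V0 + (P.V_present - V0) * t / 4.5e9;
  double hr = P.p_ref * P.mm_n2 * V / (P.pal * P.K * 1000.0);
  double tot_n2 = s[ATM] + s[ON2];
  s[ATM] = tot_n2 / (1.0 + hr);
  s[ON2] = tot_n2 - s[ATM];
  double mob = s[NHX] + s[SED];
  if (mob > 0.0 && P.Kf > 0.0 && P.S_sed > 0.0) {
    double dis;
    if (P.nF == 1.0) {
      dis = mob / (1.0 + P.Kf * P.S_sed / V);
    } else {
      double conc = 1000.0 / 14.0 / V;
      double coef = P.S_sed * 14.0 / 1000.0 * P.Kf;
      dis = freundlich_root(mob, coef, conc, 1.0 / P.nF);
    }
    s[NHX] = dis;
    s[SED] = mob - dis;
  } else {
    s[NHX] = mob;
    s[SED] = 0.0;
  }
}

void fluxes_at(const double* s, const Pars& P, double t, double* f) {
  double imp_tot = forcing(P.imp1, P.imp0, P.imptau, t) * s[ATM] / P.pal;
  double rh = forcing(P.hyd1, P.hyd0, P.hydtau, t);
  double vol_km3 = P.two_phase
    ? P.early_rate * std::min(t, P.breakpoint) +
      P.late_rate * std::max(0.0, t - P.breakpoint)
    : P.present_volume * t / 4.5e9;
  double deg_u = P.f_uma_ref * s[UMA] / P.m_uma_ref;
  double rm = forcing(P.mix1, P.mix0, P.mixtau, t);
  double exch = rm * (P.rock_u + P.rock_l);
  f[0] = forcing(P.com1, P.com0, P.comtau, t);
  f[1] = (1.0 - P.alpha_a) * imp_tot;
  f[2] = P.alpha_a * imp_tot;
  f[3] = P.lig_nox * s[ATM] / P.pal;
  f[4] = P.lig_nhx * s[ATM] / P.pal;
  f[5] = rh * s[NOX];
  f[6] = rh * 1e-3 * s[ON2];
  f[7] = (1.0 - P.eps) * s[SED] / P.D;
  f[8] = P.eps * s[SED] / P.D;
  f[9] = (vol_km3 > 0.0) ? s[CCR] * P.erosion_rate / P.thickness : 0.0;
  f[10] = P.alpha_m * deg_u;
  f[11] = (1.0 - P.alpha_m) * deg_u;
  f[12] = P.f_lma_ref * s[LMA] / P.m_lma_ref;
  f[13] = exch * s[LMA] / P.rock_l;
  f[14] = exch * s[UMA] / P.rock_u;
}

Pars unpack(const Rcpp::List& par) {
  Pars P;
  Rcpp::NumericVector v;
  v = par["comet"];        P.com1 = v[0]; P.com0 = v[1]; P.comtau = v[2];
  v = par["impact"];       P.imp1 = v[0]; P.imp0 = v[1]; P.imptau = v[2];
  v = par["hydrothermal"]; P.hyd1 = v[0]; P.hyd0 = v[1]; P.hydtau = v[2];
  v = par["mixing"];       P.mix1 = v[0]; P.mix0 = v[1]; P.mixtau = v[2];
  v = par["lightning"];    P.lig_nox = v[0]; P.lig_nhx = v[1];
  P.alpha_a = Rcpp::as<double>(par["alpha_a"]);
  v = par["degassing"];    P.alpha_m = v[0]; P.f_uma_ref = v[1];
                           P.f_lma_ref = v[2]; P.m_uma_ref = v[3];
                           P.m_lma_ref = v[4];
  v = par["subduction"];   P.D = v[0]; P.eps = v[1];
  P.erosion_rate = Rcpp::as<double>(par["erosion_rate"]);
  v = par["growth"];       P.two_phase = v[0] != 0.0; P.early_rate = v[1];
                           P.late_rate = v[2]; P.breakpoint = v[3];
                           P.present_volume = v[4]; P.thickness = v[5];
  v = par["henry"];        P.K = v[0]; P.V_present = v[1]; P.pal = v[2];
                           P.p_ref = v[3]; P.mm_n2 = v[4];
  v = par["freundlich"];   P.Kf = v[0]; P.nF = v[1]; P.S_sed = v[2];
  v = par["rock"];         P.rock_u = v[0]; P.rock_l = v[1];
  P.vol_pct = Rcpp::as<double>(par["ocean_volume_change_pct"]);
  return P;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List run_core(Rcpp::NumericVector state0, Rcpp::List par, double dt,
                    int nsteps, int stride, bool record_fluxes) {
  if (state0.size() != 8) Rcpp::stop("state must have 8 pools");
  if (nsteps < 1 || stride < 1) Rcpp::stop("nsteps and stride must be >= 1");
  Pars P = unpack(par);

  int nsamp = (nsteps - 1) / stride + 2;  // i = 0, stride, ... plus final
  Rcpp::NumericVector times(nsamp);
  Rcpp::NumericMatrix states(nsamp, 8);
  Rcpp::NumericMatrix flx(record_fluxes ? nsamp : 0, record_fluxes ? 15 : 0);

  double s[8];
  for (int j = 0; j < 8; ++j) s[j] = state0[j];
  double f[15];
  int k = 0;
  for (int i = 0; i < nsteps; ++i) {
    double t = i * dt;
    if (i % stride == 0) {
      times[k] = t;
      for (int j = 0; j < 8; ++j) states(k, j) = s[j];
      if (record_fluxes) {
        fluxes_at(s, P, t, f);
        for (int j = 0; j < 15; ++j) flx(k, j) = f[j];
      }
      ++k;
    }
    step(s, P, t, dt);
  }
  times[k] = nsteps * dt;
  for (int j = 0; j < 8; ++j) states(k, j) = s[j];
  if (record_fluxes) {
    fluxes_at(s, P, nsteps * dt, f);
    for (int j = 0; j < 15; ++j) flx(k, j) = f[j];
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("times") = times,
                                      Rcpp::Named("states") = states);
  if (record_fluxes) out["fluxes"] = flx;
  return out;
}
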