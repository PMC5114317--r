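// Ten Tusscher-Panfilov 2006 human ventricular myocyte model and a 1D
// transmural monodomain strand. Gates are advanced with the Rush-Larsen
// scheme, concentrations and voltage with forward Euler; intracellular
// calcium buffering uses the standard rapid-buffering quadratic update.
// Units: ms, mV, pA/pF, mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// state vector layout (19 variables)
enum StateIdx {
  iV = 0, iNai, iKi, iCai, iCaSS, iCaSR, iRbar,
  im, ih, ij, ixr1, ixr2, ixs, ir, is_, id_, if_, if2_, ifcass,
  NSTATE
};

// physical constants
static const double Rgas = 8314.472;   // J/(kmol K)
static const double Temp = 310.0;      // K
static const double Frd  = 96485.3415; // C/mol
static const double RTF  = Rgas * Temp / Frd;

// extracellular concentrations (mM) and cell geometry
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
static const double Cm = 0.185;        // uF
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468; // uL

// buffering
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

// SR release / uptake
static const double Kup = 0.00025, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;

// exchangers / pumps
static const double pKNa = 0.03;
static const double KmK = 1.0, KmNa = 40.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35;
static const double KpCa = 0.0005;

struct Params {
  double gNa, gCaL, gKr, gKs, gK1, gto;
  double gpCa, gpK, gbNa, gbCa, PNaK, kNaCa, Vmaxup, Vrel;
  int subtype; // 0 = endo, 1 = epi, 2 = M (s-gate kinetics differ for endo)
};

static Params params_from_vec(const NumericVector& p, int subtype) {
  Params q;
  q.gNa = p["gNa"];   q.gCaL = p["gCaL"]; q.gKr = p["gKr"]; q.gKs = p["gKs"];
  q.gK1 = p["gK1"];   q.gto = p["gto"];   q.gpCa = p["gpCa"]; q.gpK = p["gpK"];
  q.gbNa = p["gbNa"]; q.gbCa = p["gbCa"]; q.PNaK = p["PNaK"];
  q.kNaCa = p["kNaCa"]; q.Vmaxup = p["Vmaxup"]; q.Vrel = p["Vrel"];
  q.subtype = subtype;
  return q;
}

// one forward step; Istim in pA/pF, depolarizing stimulus is negative
static inline void tt_step_one(double* s, const Params& p, double dt,
                               double Istim) {
  const double V = s[iV];
  const double Nai = s[iNai], Ki = s[iKi];
  const double Cai = s[iCai], CaSS = s[iCaSS], CaSR = s[iCaSR];

  const double Ek  = RTF * std::log(Ko / Ki);
  const double Ena = RTF * std::log(Nao / Nai);
  const double Eks = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTF * std::log(Cao / Cai);

  // ---- currents (old gate values) ----
  const double INa = p.gNa * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - Ena);

  double Vm15 = V - 15.0;
  if (std::fabs(Vm15) < 1e-6) Vm15 = 1e-6; // removable singularity guard
  const double expv = std::exp(2.0 * Vm15 / RTF);
  const double ICaL = p.gCaL * s[id_] * s[if_] * s[if2_] * s[ifcass] * 4.0 *
                      Vm15 * (Frd / RTF) *
                      (0.25 * CaSS * expv - Cao) / (expv - 1.0);

  const double Ito = p.gto * s[ir] * s[is_] * (V - Ek);
  const double IKr = p.gKr * std::sqrt(Ko / 5.4) * s[ixr1] * s[ixr2] * (V - Ek);
  const double IKs = p.gKs * s[ixs] * s[ixs] * (V - Eks);

  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                      std::exp(0.1 * (V - Ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - Ek)));
  const double IK1 = p.gK1 * (aK1 / (aK1 + bK1)) * (V - Ek);

  const double INaCa =
      p.kNaCa *
      (std::exp(gam * V / RTF) * Nai * Nai * Nai * Cao -
       std::exp((gam - 1.0) * V / RTF) * Nao * Nao * Nao * Cai * 2.5) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * V / RTF)));

  const double INaK = p.PNaK * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
                      (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                       0.0353 * std::exp(-V / RTF));

  const double IpCa = p.gpCa * Cai / (Cai + KpCa);
  const double IpK  = p.gpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = p.gbNa * (V - Ena);
  const double IbCa = p.gbCa * (V - Eca);

  // ---- gate updates (Rush-Larsen) ----
  // INa gates
  double inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  double tau = am * bm;
  s[im] = inf + (s[im] - inf) * std::exp(-dt / tau);

  inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double ah, bh;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
  }
  tau = 1.0 / (ah + bh);
  s[ih] = inf + (s[ih] - inf) * std::exp(-dt / tau);

  double aj, bj;
  if (V >= -40.0) {
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    aj = (-25428.0 * std::exp(0.2444 * V) -
          6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  tau = 1.0 / (aj + bj);
  s[ij] = inf + (s[ij] - inf) * std::exp(-dt / tau);

  // IKr gates
  inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  tau = a * b;
  s[ixr1] = inf + (s[ixr1] - inf) * std::exp(-dt / tau);

  inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  tau = a * b;
  s[ixr2] = inf + (s[ixr2] - inf) * std::exp(-dt / tau);

  // IKs gate
  inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  tau = a * b + 80.0;
  s[ixs] = inf + (s[ixs] - inf) * std::exp(-dt / tau);

  // Ito gates
  inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  s[ir] = inf + (s[ir] - inf) * std::exp(-dt / tau);

  if (p.subtype == 0) { // endo
    inf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    tau = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {              // epi and M
    inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
          5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  s[is_] = inf + (s[is_] - inf) * std::exp(-dt / tau);

  // ICaL gates
  inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  tau = a * b + c;
  s[id_] = inf + (s[id_] - inf) * std::exp(-dt / tau);

  inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  a = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0);
  b = 200.0 / (1.0 + std::exp((13.0 - V) / 10.0));
  c = 180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  tau = a + b + c;
  s[if_] = inf + (s[if_] - inf) * std::exp(-dt / tau);

  inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  a = 600.0 * std::exp(-(V + 25.0) * (V + 25.0) / 170.0);
  b = 31.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  c = 16.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  tau = a + b + c;
  s[if2_] = inf + (s[if2_] - inf) * std::exp(-dt / tau);

  inf = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  tau = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;
  s[ifcass] = inf + (s[ifcass] - inf) * std::exp(-dt / tau);

  // ---- calcium dynamics ----
  const double kcasr = maxsr - (maxsr - minsr) /
                                  (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
  const double k1 = k1p / kcasr;
  const double k2 = k2p * kcasr;
  s[iRbar] += dt * (-k2 * CaSS * s[iRbar] + k4 * (1.0 - s[iRbar]));
  const double O = k1 * CaSS * CaSS * s[iRbar] / (k3 + k1 * CaSS * CaSS);

  const double Irel  = p.Vrel * O * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup   = p.Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  // SR calcium (rapid buffering, quadratic solve)
  {
    const double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
    const double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
    s[iCaSR] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
  }
  // subspace calcium
  {
    const double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
    const double dCaSS =
        dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
              (-ICaL * Cm / (2.0 * Vss * Frd)));
    const double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
    const double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
    s[iCaSS] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;
  }
  // cytosolic calcium
  {
    const double CaBuf = Bufc * Cai / (Cai + Kbufc);
    const double dCai =
        dt * (-(IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frd) -
              (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
    const double cc = Kbufc * (CaBuf + dCai + Cai);
    s[iCai] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }

  // ---- Na+, K+, voltage ----
  s[iNai] += -dt * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frd);
  s[iKi]  += -dt * (Istim + IK1 + Ito + IKr + IKs + IpK - 2.0 * INaK) * Cm /
             (Vc * Frd);

  const double Itot = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa +
                      INaK + INaCa + IpCa + IpK + Istim;
  s[iV] -= dt * Itot;
}

static void check_finite(const double* s, const char* where) {
  for (int k = 0; k < NSTATE; ++k)
    if (!R_finite(s[k]))
      stop("non-finite state encountered in %s (numerical instability)", where);
}

// [[Rcpp::export]]
NumericVector tt_step_cpp(NumericVector state, NumericVector params,
                          int subtype, double dt, double istim) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  Params p = params_from_vec(params, subtype);
  NumericVector out = clone(state);
  tt_step_one(REAL(out), p, dt, istim);
  check_finite(REAL(out), "tt_step");
  out.attr("names") = state.attr("names");
  return out;
}

// Pace a single cell for nbeats at cycle length cl; record the final beat's
// voltage every sample_every steps. Returns the trace and the final state.
// [[Rcpp::export]]
List tt_pace_cpp(NumericVector state, NumericVector params, int subtype,
                 double cl, int nbeats, double dt, double stim_amp,
                 double stim_dur, int sample_every) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  Params p = params_from_vec(params, subtype);
  std::vector<double> s(REAL(state), REAL(state) + NSTATE);

  const int steps_per_beat = (int)std::round(cl / dt);
  const int stim_steps = (int)std::round(stim_dur / dt);
  const int nsamp = steps_per_beat / sample_every + 1;
  NumericVector tout(nsamp), vout(nsamp), caiout(nsamp);

  for (int beat = 0; beat < nbeats; ++beat) {
    const bool rec = (beat == nbeats - 1);
    int isamp = 0;
    for (int k = 0; k < steps_per_beat; ++k) {
      if (rec && (k % sample_every == 0)) {
        tout[isamp] = k * dt;
        vout[isamp] = s[iV];
        caiout[isamp] = s[iCai];
        ++isamp;
      }
      const double istim = (k < stim_steps) ? -stim_amp : 0.0;
      tt_step_one(s.data(), p, dt, istim);
    }
    check_finite(s.data(), "tt_pace (end of beat)");
    if (rec && isamp < nsamp) {
      tout[isamp] = steps_per_beat * dt;
      vout[isamp] = s[iV];
      caiout[isamp] = s[iCai];
    }
  }
  NumericVector fin(NSTATE);
  std::copy(s.begin(), s.end(), fin.begin());
  fin.attr("names") = state.attr("names");
  return List::create(_["time"] = tout, _["V"] = vout, _["Cai"] = caiout,
                      _["state"] = fin);
}

// Monodomain 1D strand, operator-split: reaction per cell then explicit
// diffusion with no-flux boundaries. states: NSTATE x ncell matrix;
// params_mat: nparam-named-rows irrelevant -- one column of conductance
// vector per cell is wasteful, so a single params vector per subtype group
// is passed instead: params_list has one NumericVector per cell group and
// group index per cell. Stimulus applied to the first nstim cells.
// Records V every sample_every steps for the final beat.
// [[Rcpp::export]]
List tt_strand_cpp(NumericMatrix states, List params_list,
                   IntegerVector group, IntegerVector subtype_per_group,
                   double diff_coef, double dx, double cl, int nbeats,
                   double dt, double stim_amp, double stim_dur, int nstim,
                   int sample_every) {
  const int ncell = states.ncol();
  if (states.nrow() != NSTATE) stop("states must have %d rows", NSTATE);
  const int ngroup = params_list.size();
  std::vector<Params> pars(ngroup);
  for (int g = 0; g < ngroup; ++g)
    pars[g] = params_from_vec(params_list[g], subtype_per_group[g]);

  std::vector<double> s(REAL(states), REAL(states) + NSTATE * ncell);
  std::vector<double> vnew(ncell);

  const int steps_per_beat = (int)std::round(cl / dt);
  const int stim_steps = (int)std::round(stim_dur / dt);
  const double r = diff_coef * dt / (dx * dx);
  if (r > 0.5) stop("diffusion step unstable: D*dt/dx^2 = %.3f > 0.5", r);

  const int nsamp = steps_per_beat / sample_every;
  NumericMatrix vfield(nsamp, ncell);
  NumericVector tout(nsamp);

  for (int beat = 0; beat < nbeats; ++beat) {
    const bool rec = (beat == nbeats - 1);
    int isamp = 0;
    for (int k = 0; k < steps_per_beat; ++k) {
      if (rec && (k % sample_every == 0) && isamp < nsamp) {
        tout[isamp] = k * dt;
        for (int i = 0; i < ncell; ++i) vfield(isamp, i) = s[i * NSTATE + iV];
        ++isamp;
      }
      // reaction
      for (int i = 0; i < ncell; ++i) {
        const double istim =
            (k < stim_steps && i < nstim) ? -stim_amp : 0.0;
        tt_step_one(&s[i * NSTATE], pars[group[i]], dt, istim);
      }
      // diffusion on V, no-flux (mirror) boundaries
      for (int i = 0; i < ncell; ++i) {
        const double vl = s[(i == 0 ? 1 : i - 1) * NSTATE + iV];
        const double vr = s[(i == ncell - 1 ? ncell - 2 : i + 1) * NSTATE + iV];
        vnew[i] = s[i * NSTATE + iV] + r * (vl - 2.0 * s[i * NSTATE + iV] + vr);
      }
      for (int i = 0; i < ncell; ++i) s[i * NSTATE + iV] = vnew[i];
    }
    for (int i = 0; i < ncell; ++i)
      check_finite(&s[i * NSTATE], "tt_strand (end of beat)");
  }

  NumericMatrix fin(NSTATE, ncell);
  std::copy(s.begin(), s.end(), fin.begin());
  return List::create(_["time"] = tout, _["V"] = vfield, _["state"] = fin);
}
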