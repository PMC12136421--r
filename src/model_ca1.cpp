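#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout. Must match .ca1_param_order in R/model.R.
enum {
  P_C = 0, P_GL, P_EL, P_EK, P_ENA, P_ECA, P_EH,
  P_GNAT, P_GNAP, P_GKDR, P_GKM, P_GKA, P_GHCA, P_GFKCA, P_GSKCA,
  P_GH, P_GAC, P_NCOMP,
  P_NU, P_TAUHCA, P_AC, P_AQ,
  P_THM, P_SGM, P_THH, P_SGH, P_THHT, P_SGHT,
  P_THP, P_SGP, P_THN, P_SGN, P_THNT, P_SGNT,
  P_THZ, P_SGZ, P_TAUZ, P_THA, P_SGA, P_THB, P_SGB, P_TAUB,
  P_THR, P_SGR, P_TAUR, P_THC, P_SGC, P_TAUC, P_TAUQ,
  P_THT, P_SGT, P_TAUT,
  P_D, P_CD, P_GLD, P_ELD,
  P_NPAR
};

// State layout: 0 V_soma, 1 h, 2 n, 3 z, 4 b, 5 r, 6 c, 7 q, 8 Ca, 9 V_dend, 10 t
static const int NSTATE = 11;

static inline double xinf(double V, double th, double sg) {
  return 1.0 / (1.0 + std::exp(-(V - th) / sg));
}

static void ca1_deriv(const double *p, const double *y,
                      double i_soma, double i_dend, double *dy) {
  const double V = y[0], h = y[1], n = y[2], z = y[3], b = y[4];
  const double r = y[5], c = y[6], q = y[7], Ca = y[8];
  const int ncomp = (int)p[P_NCOMP];

  // instantaneous gates
  const double m = xinf(V, p[P_THM], p[P_SGM]);
  const double pp = xinf(V, p[P_THP], p[P_SGP]);
  const double a = xinf(V, p[P_THA], p[P_SGA]);
  const double dinf = (Ca <= 0.0) ? 0.0 : Ca / (Ca + p[P_AC]);

  const double INaT = p[P_GNAT] * m * m * m * h * (V - p[P_ENA]);
  const double INaP = p[P_GNAP] * pp * (V - p[P_ENA]);
  const double IKdr = p[P_GKDR] * n * n * n * n * (V - p[P_EK]);
  const double IKM  = p[P_GKM] * z * (V - p[P_EK]);
  const double IKA  = p[P_GKA] * a * a * a * b * (V - p[P_EK]);
  const double IHCa = p[P_GHCA] * r * r * (V - p[P_ECA]);
  const double IfK  = p[P_GFKCA] * dinf * c * (V - p[P_EK]);
  const double IsK  = p[P_GSKCA] * q * (V - p[P_EK]);
  double Iax = 0.0;
  if (ncomp > 1) Iax = p[P_GAC] * (V - y[9]);

  dy[0] = (-p[P_GL] * (V - p[P_EL])
           - INaT - INaP - IKdr - IKM - IKA - IHCa - IfK - IsK
           - Iax + i_soma) / p[P_C];

  const double tauh = 0.1 + 0.75 * xinf(V, p[P_THHT], p[P_SGHT]);
  const double taun = 0.1 + 0.5  * xinf(V, p[P_THNT], p[P_SGNT]);
  dy[1] = (xinf(V, p[P_THH], p[P_SGH]) - h) / tauh;
  dy[2] = (xinf(V, p[P_THN], p[P_SGN]) - n) / taun;
  dy[3] = (xinf(V, p[P_THZ], p[P_SGZ]) - z) / p[P_TAUZ];
  dy[4] = (xinf(V, p[P_THB], p[P_SGB]) - b) / p[P_TAUB];
  dy[5] = (xinf(V, p[P_THR], p[P_SGR]) - r) / p[P_TAUR];
  dy[6] = (xinf(V, p[P_THC], p[P_SGC]) - c) / p[P_TAUC];

  const double ca4 = Ca * Ca * Ca * Ca;
  const double aq = p[P_AQ], aq4 = aq * aq * aq * aq;
  const double qinf = (Ca <= 0.0) ? 0.0 : ca4 / (ca4 + aq4);
  dy[7] = (qinf - q) / p[P_TAUQ];

  dy[8] = -p[P_NU] * IHCa - Ca / p[P_TAUHCA];

  if (ncomp > 1) {
    const double Vd = y[9], t = y[10];
    const double Ih = p[P_GH] * t * (Vd - p[P_EH]);
    const double Iaxd = p[P_GAC] * (Vd - V);
    dy[9] = (-p[P_GLD] * (Vd - p[P_ELD]) - Ih - Iaxd + i_dend) / p[P_CD];
    dy[10] = (xinf(Vd, p[P_THT], p[P_SGT]) - t) / p[P_TAUT];
  } else {
    dy[9] = 0.0;
    dy[10] = 0.0;
  }
}

// Single derivative evaluation (reference/testing hook).
// [[Rcpp::export]]
NumericVector dstate_ca1_cpp(NumericVector par, NumericVector state,
                             double i_soma, double i_dend) {
  if (par.size() != P_NPAR) stop("parameter vector has wrong length");
  if (state.size() != NSTATE) stop("state vector has wrong length");
  NumericVector out(NSTATE);
  ca1_deriv(par.begin(), state.begin(), i_soma, i_dend, out.begin());
  return out;
}

// Euler-Maruyama integration. i_soma/i_dend give the applied current at each
// step; somatic voltage receives a Gaussian increment of s.d. sqrt(2*D*dt)/C
// per step (Langevin current sqrt(2D) xi(t)). Uses R's RNG so seeding via
// set.seed() on the R side fully determines the path.
// [[Rcpp::export]]
List sim_ca1_cpp(NumericVector par, NumericVector i_soma, NumericVector i_dend,
                 double dt, NumericVector init, bool record_gates) {
  if (par.size() != P_NPAR) stop("parameter vector has wrong length");
  if (init.size() != NSTATE) stop("initial state has wrong length");
  const int nstep = i_soma.size();
  if (i_dend.size() != nstep) stop("stimulus lengths differ");
  const int ncomp = (int)par[P_NCOMP];

  const double noise_sd = std::sqrt(2.0 * par[P_D] * dt) / par[P_C];

  NumericVector Vs(nstep), Vd(ncomp > 1 ? nstep : 0), CaOut(nstep);
  NumericMatrix gates(record_gates ? nstep : 0, 8);

  double y[NSTATE], dy[NSTATE];
  for (int k = 0; k < NSTATE; ++k) y[k] = init[k];

  for (int i = 0; i < nstep; ++i) {
    Vs[i] = y[0];
    if (ncomp > 1) Vd[i] = y[9];
    CaOut[i] = y[8];
    if (record_gates) {
      for (int k = 0; k < 7; ++k) gates(i, k) = y[1 + k]; // h n z b r c q
      gates(i, 7) = y[10];                                // t
    }
    ca1_deriv(par.begin(), y, i_soma[i], i_dend[i], dy);
    for (int k = 0; k < NSTATE; ++k) y[k] += dt * dy[k];
    if (noise_sd > 0.0) y[0] += noise_sd * R::norm_rand();
    if (!(y[0] > -1e6 && y[0] < 1e6))
      stop("simulation diverged (non-finite voltage) at t = %f ms", (i + 1) * dt);
  }

  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = y[k];

  return List::create(_["v_soma"] = Vs, _["v_dend"] = Vd, _["ca"] = CaOut,
                      _["gates"] = gates, _["final_state"] = fin);
}
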