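/* Compiled right-hand side of the reduced mouse SAN cell model.
 *
 * This is a line-for-line translation of the reference R implementation in
 * R/currents.R (sanc_rhs / compute_currents); a test asserts agreement at
 * random states.  Units: s, mV, mM, pA, pF, pL, nS.
 *
 * The parameter vector layout must match sanc_param_names() in R/params.R;
 * the last eight slots carry the drive for the current protocol segment
 * (sna/pna endpoints with linear interpolation between seg_t0 and seg_t1,
 * plus constant body temperature and LCR multiplier).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 11
#define N_PAR   70
#define N_OUT   13

/* state indices */
#define iV   0
#define iDL  1
#define iFL  2
#define iFCA 3
#define iDT  4
#define iFT  5
#define iY   6
#define iN   7
#define iNAI 8
#define iCAI 9
#define iPKA 10

enum {
  p_cm, p_vi, p_nao, p_ko, p_cao, p_ki,
  p_g_cal, p_g_cat, p_g_hcn, p_g_k, p_g_kach, p_g_bna, p_g_bca,
  p_e_cal, p_e_cat, p_e_h,
  p_inak_max, p_km_nak, p_nh_nak, p_km_ko,
  p_k_ncx, p_d_ncx, p_gamma_ncx,
  p_f_na_hcn, p_f_cab, p_km_fca,
  p_tau_dl, p_tau_fl, p_tau_dt, p_tau_ft, p_tau_y, p_tau_n, p_tau_fca,
  p_v_dl, p_k_dl, p_v_fl, p_k_fl, p_v_dt, p_k_dt, p_v_ft, p_k_ft,
  p_v_y, p_k_y, p_v_n, p_k_n, p_v_kach, p_k_kach,
  p_a_cal, p_a_cat, p_a_hcn, p_a_kach, p_a2_sym, p_a2_kach, p_mod_floor,
  p_tau_pka,
  p_ipca_max, p_km_pca, p_s_hcn,
  p_q10_rate, p_q10_cond, p_q10_ca, p_t_ref,
  p_sna0, p_sna1, p_pna0, p_pna1, p_seg_t0, p_seg_t1, p_bt, p_lcr
};

static double parms[N_PAR];

static double ginf(double V, double vh, double k)
{
  return 1.0 / (1.0 + exp((vh - V) / k));
}

static void sanc_core(double t, const double *y, const double *p,
                      double *dy, double *out)
{
  const double V = y[iV], dL = y[iDL], fL = y[iFL], fCa = y[iFCA];
  const double dT = y[iDT], fT = y[iFT], yh = y[iY], n = y[iN];
  const double Nai = y[iNAI], Cai = y[iCAI], pka = y[iPKA];

  /* drive: linear in t across the segment, constant outside it */
  double frac = 0.0;
  if (p[p_seg_t1] > p[p_seg_t0])
    frac = (t - p[p_seg_t0]) / (p[p_seg_t1] - p[p_seg_t0]);
  if (frac < 0.0) frac = 0.0;
  if (frac > 1.0) frac = 1.0;
  const double sna = p[p_sna0] + frac * (p[p_sna1] - p[p_sna0]);
  const double pna = p[p_pna0] + frac * (p[p_pna1] - p[p_pna0]);
  const double bt  = p[p_bt], lcr = p[p_lcr];

  const double phi_r = pow(p[p_q10_rate], (bt - p[p_t_ref]) / 10.0);
  const double phi_g = pow(p[p_q10_cond], (bt - p[p_t_ref]) / 10.0);
  /* Ca-channel availability is the most temperature-sensitive conductance;
   * its steeper Q10 makes warm (waking) temperatures arrhythmogenic */
  const double phi_ca = pow(p[p_q10_ca], (bt - p[p_t_ref]) / 10.0);
  const double rtf = 0.0861733 * (273.15 + bt);
  const double e_k  = rtf * log(p[p_ko] / p[p_ki]);
  const double e_na = rtf * log(p[p_nao] / Nai);

  /* autonomic targets: multiplicative conductance scaling, floored at 0 */
  /* sympathetic targets keep a basal fraction of their conductance when
   * drive is withdrawn (denervation does not abolish channel activity) */
  const double fl0 = p[p_mod_floor];
  /* Ca-channel upregulation follows the slow phosphorylation state (pka),
   * so a sympathetic surge speeds pacing acutely (fast cAMP action on
   * HCN below) while the Ca-load escalation develops over tens of
   * seconds */
  const double ds = pka - 1.0, ds2 = (pka > 1.0) ? ds * ds : 0.0;
  double m_cal  = 1.0 + p[p_a_cal] * ds + p[p_a2_sym] * ds2;
  if (m_cal < fl0) m_cal = fl0;
  double m_cat  = 1.0 + p[p_a_cat] * ds + p[p_a2_sym] * ds2;
  if (m_cat < fl0) m_cat = fl0;
  double m_hcn  = 1.0 + p[p_a_hcn]  * (sna - 1.0); if (m_hcn  < fl0) m_hcn  = fl0;
  /* muscarinic sensitisation beyond twice-baseline vagal tone: the
   * quadratic term engages only at the deep parasympathetic levels of
   * the postictal phase */
  const double dp = pna - 1.0;
  const double dq = (pna > 2.0) ? (pna - 2.0) : 0.0;
  /* below baseline the current tracks transmitter withdrawal at unit
   * gain: no acetylcholine, no muscarinic current */
  double m_kach = (pna < 1.0)
    ? pna
    : 1.0 + p[p_a_kach] * dp + p[p_a2_kach] * dq * dq;
  if (m_kach < 0) m_kach = 0;

  const double i_cal = p[p_g_cal] * phi_ca * m_cal * dL * fL * fCa * (V - p[p_e_cal]);
  const double i_cat = p[p_g_cat] * phi_ca * m_cat * dT * fT * (V - p[p_e_cat]);
  const double i_hcn = p[p_g_hcn] * phi_g * m_hcn * lcr * yh * (V - p[p_e_h]);
  const double i_k   = p[p_g_k]   * phi_g * n * (V - e_k);
  const double r_kach = ginf(V, p[p_v_kach], p[p_k_kach]);
  const double i_kach = p[p_g_kach] * phi_g * m_kach * r_kach * (V - e_k);

  const double hill = pow(Nai, p[p_nh_nak]);
  const double i_nak = p[p_inak_max] * phi_g *
    hill / (hill + pow(p[p_km_nak], p[p_nh_nak])) *
    p[p_ko] / (p[p_ko] + p[p_km_ko]);

  const double na3 = Nai * Nai * Nai;
  const double nao3 = p[p_nao] * p[p_nao] * p[p_nao];
  const double ef = exp(p[p_gamma_ncx] * V / rtf);
  const double er = exp(-(1.0 - p[p_gamma_ncx]) * V / rtf);
  const double i_ncx = p[p_k_ncx] * phi_g *
    (na3 * p[p_cao] * ef - nao3 * Cai * er) /
    (1.0 + p[p_d_ncx] * (Cai * nao3 + p[p_cao] * na3));

  const double i_bna = p[p_g_bna] * (V - e_na);
  const double i_bca = p[p_g_bca] * (V - p[p_e_cal]);
  const double i_pca = p[p_ipca_max] * phi_g * Cai / (Cai + p[p_km_pca]);

  const double i_tot = i_cal + i_cat + i_hcn + i_k + i_kach +
                       i_nak + i_ncx + i_bna + i_bca + i_pca;

  dy[iV]   = -1000.0 * i_tot / p[p_cm];  /* pA/pF = mV/ms; time unit is s */
  dy[iDL]  = phi_r * (ginf(V, p[p_v_dl], p[p_k_dl]) - dL) / p[p_tau_dl];
  dy[iFL]  = phi_r * (ginf(V, p[p_v_fl], p[p_k_fl]) - fL) / p[p_tau_fl];
  dy[iDT]  = phi_r * (ginf(V, p[p_v_dt], p[p_k_dt]) - dT) / p[p_tau_dt];
  dy[iFT]  = phi_r * (ginf(V, p[p_v_ft], p[p_k_ft]) - fT) / p[p_tau_ft];
  const double v_y_eff = p[p_v_y] + p[p_s_hcn] * tanh(sna - 1.0);
  dy[iY]   = phi_r * (ginf(V, v_y_eff, p[p_k_y]) - yh) / p[p_tau_y];
  dy[iN]   = phi_r * (ginf(V, p[p_v_n],  p[p_k_n])  - n)  / p[p_tau_n];
  const double fca_inf = p[p_km_fca] / (p[p_km_fca] + Cai);
  dy[iFCA] = phi_r * (fca_inf - fCa) / p[p_tau_fca];

  /* ion bookkeeping: pA / (F * pL) * 1000 -> mM/s */
  const double fv = 96485.0 * p[p_vi];
  dy[iPKA] = (sna - pka) / p[p_tau_pka];
  dy[iNAI] = -1000.0 *
    (i_bna + p[p_f_na_hcn] * i_hcn + 3.0 * i_nak + 3.0 * i_ncx) / fv;
  dy[iCAI] = -p[p_f_cab] * 1000.0 * (i_cal + i_cat + i_bca + i_pca - 2.0 * i_ncx) / (2.0 * fv);

  out[0] = i_cal;  out[1] = i_cat; out[2] = i_hcn; out[3] = i_k;
  out[4] = i_kach; out[5] = i_nak; out[6] = i_ncx; out[7] = i_bna;
  out[8] = i_bca;  out[9] = i_pca; out[10] = i_tot;
  out[11] = sna;   out[12] = pna;
}

/* deSolve compiled-code interface */
void sanc_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PAR;
  odeparms(&n, parms);
}

void sanc_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  double out[N_OUT];
  sanc_core(*t, y, parms, ydot, out);
  if (ip[0] >= N_OUT)
    for (int i = 0; i < N_OUT; i++) yout[i] = out[i];
}

/* direct evaluation, used by tests to compare against the R reference */
SEXP C_sanc_rhs(SEXP t, SEXP y, SEXP p)
{
  if (LENGTH(y) != N_STATE) error("state vector must have %d entries", N_STATE);
  if (LENGTH(p) != N_PAR) error("parameter vector must have %d entries", N_PAR);
  SEXP dy  = PROTECT(allocVector(REALSXP, N_STATE));
  SEXP out = PROTECT(allocVector(REALSXP, N_OUT));
  sanc_core(asReal(t), REAL(y), REAL(p), REAL(dy), REAL(out));
  SEXP res = PROTECT(allocVector(VECSXP, 2));
  SET_VECTOR_ELT(res, 0, dy);
  SET_VECTOR_ELT(res, 1, out);
  SEXP nm = PROTECT(allocVector(STRSXP, 2));
  SET_STRING_ELT(nm, 0, mkChar("dstate"));
  SET_STRING_ELT(nm, 1, mkChar("out"));
  setAttrib(res, R_NamesSymbol, nm);
  UNPROTECT(4);
  return res;
}

static const R_CallMethodDef call_entries[] = {
  {"C_sanc_rhs", (DL_FUNC) &C_sanc_rhs, 3},
  {NULL, NULL, 0}
};

/* registered so deSolve can resolve them by name with dynamic lookup off */
static const R_CMethodDef c_entries[] = {
  {"sanc_derivs",  (DL_FUNC) &sanc_derivs,  6},
  {"sanc_initmod", (DL_FUNC) &sanc_initmod, 1},
  {NULL, NULL, 0}
};

void R_init_sancpace(DllInfo *dll)
{
  R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
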