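// Core ODE right-hand sides and integrators for the compartmentalized
// beta1-adrenergic signaling / mouse ventricular myocyte model.
//
// All rate constants, concentrations and conductances are taken from the
// parameter vector (built in R from the shipped ledger); this file contains
// only the structural form of the equations.
//
// Unit system: time ms, concentration uM, voltage mV, current pA/pF.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include "model_def.h"

using namespace Rcpp;

// ---- registries -----------------------------------------------------------
#define BM_ENUM(name) P_##name,
enum BmParam { BM_PARAMS(BM_ENUM) BM_NPAR };
#undef BM_ENUM
#define BM_ENUM(name) S_##name,
enum BmSigState { BM_SIG_STATES(BM_ENUM) BM_NSIG };
#undef BM_ENUM
#define BM_ENUM(name) E_##name,
enum BmCellState { BM_CELL_STATES(BM_ENUM) BM_NCELL };
#undef BM_ENUM
#define BM_ENUM(name) CUR_##name,
enum BmCurrent { BM_CURRENTS(BM_ENUM) BM_NCUR };
#undef BM_ENUM

#define BM_NAME(name) #name,
static const char* BM_PNAMES[] = { BM_PARAMS(BM_NAME) };
static const char* BM_SNAMES[] = { BM_SIG_STATES(BM_NAME) };
static const char* BM_ENAMES[] = { BM_CELL_STATES(BM_NAME) };
static const char* BM_CNAMES[] = { BM_CURRENTS(BM_NAME) };
#undef BM_NAME

// ---- drug / protocol context ---------------------------------------------
struct Ctx {
  double iso;        // isoproterenol, uM
  double pde3_mult;  // selective PDE3 inhibition multiplier (1 = none)
  double pde4_mult;
  double ibmx_mult;  // non-selective PDE inhibition multiplier
  double pka_scale;  // scales PKA_tot (0 emulates H-89)
  double pp_scale;   // scales PP1/PP2A activity (0.35 emulates Calyculin A)
  int block_cav, block_ecav; // L-type population block
  int no_cicr;       // Jrel = 0 ("heavy buffer" clamp condition)
  int clamp;         // voltage clamp: V held fixed
  double clamp_V;
  int pacing;        // current stimulus train on
  double stim_t0, stim_period;
};

static Ctx ctx_from_list(const List& l) {
  Ctx c;
  c.iso = as<double>(l["iso"]);
  c.pde3_mult = as<double>(l["pde3_mult"]);
  c.pde4_mult = as<double>(l["pde4_mult"]);
  c.ibmx_mult = as<double>(l["ibmx_mult"]);
  c.pka_scale = as<double>(l["pka_scale"]);
  c.pp_scale  = as<double>(l["pp_scale"]);
  c.block_cav  = as<int>(l["block_cav"]);
  c.block_ecav = as<int>(l["block_ecav"]);
  c.no_cicr = as<int>(l["no_cicr"]);
  c.clamp   = as<int>(l["clamp"]);
  c.clamp_V = as<double>(l["clamp_V"]);
  c.pacing  = as<int>(l["pacing"]);
  c.stim_t0 = as<double>(l["stim_t0"]);
  c.stim_period = as<double>(l["stim_period"]);
  return c;
}

// ---------------------------------------------------------------------------
// Receptor module: ligand-receptor-G-protein equilibrium (closed form).
// Conservation laws
//   R_tot_np = R + LR + LRG + RG,   Gs_avail = Gs + LRG + RG
// with [LR] = L R / K_L, [LRG] = L R G/(K_L K_H), [RG] = R G/K_C reduce to a
// quadratic in free R (substituting G = Gs_avail/(1+qR), q = L/(K_L K_H)+1/K_C).
// ---------------------------------------------------------------------------
struct RecEq { double R, G, LR, LRG, RG; };

static RecEq receptor_equilibrium(double L, double Rt, double Gt,
                                  double KL, double KH, double KC) {
  RecEq out{0, Gt, 0, 0, 0};
  if (Rt <= 0.0) return out;
  const double q = L/(KL*KH) + 1.0/KC;
  const double u = 1.0 + L/KL;
  double R;
  if (q*Rt < 1e-14) {            // negligible G coupling
    R = Rt/u;
  } else {
    const double a = q*u;
    const double b = u + q*Gt - Rt*q;
    const double cc = -Rt;
    R = (-b + std::sqrt(b*b - 4.0*a*cc)) / (2.0*a);
  }
  if (R < 0) R = 0;
  const double G = Gt/(1.0 + q*R);
  out.R = R; out.G = G;
  out.LR = L*R/KL;
  out.LRG = L*R*G/(KL*KH);
  out.RG = R*G/KC;
  return out;
}

// PDE degradation rate (local uM/ms) for one compartment
static double pde_rate(double c, double conc2, double conc3, double conc4,
                       double f3, double f4, const double* p, const Ctx& cx) {
  const double r2 = p[P_kcat_PDE2]*conc2 * c/(c + p[P_Km_PDE2]);
  const double r3 = p[P_kcat_PDE3]*conc3 * (1.0 + p[P_delta_PDE3_phos]*f3) *
                    c/(c + p[P_Km_PDE3]) * cx.pde3_mult;
  const double r4 = p[P_kcat_PDE4]*conc4 * (1.0 + p[P_delta_PDE4_phos]*f4) *
                    c/(c + p[P_Km_PDE4]) * cx.pde4_mult;
  return cx.ibmx_mult * (r2 + r3 + r4);
}

// AC synthesis rate (local uM/ms): lumped basal + Gsa activation, Gsbg boost
static double ac_rate(double gsa, double gsbg, double conc, double kcat,
                      double bfrac, double Kgsa, double h,
                      double sbg, double Kbg) {
  double act;
  if (gsa <= 0.0) act = 0.0;
  else {
    const double gh = std::pow(gsa, h);
    act = gh/(gh + std::pow(Kgsa, h));
  }
  const double boost = 1.0 + (gsbg > 0 ? sbg*gsbg/(gsbg + Kbg) : 0.0);
  return conc*kcat*(bfrac + (1.0 - bfrac)*act)*boost;
}

// helper: free PP1 in cytosol from the I-1 steady-state complex (quadratic)
static void pp1_inhib1(double I1p_tot, double PP1_tot, double K,
                       double* pp1_free, double* cmplx, double* i1p_free) {
  const double b = I1p_tot + PP1_tot + K;
  double disc = b*b - 4.0*I1p_tot*PP1_tot;
  if (disc < 0) disc = 0;
  double cm = 0.5*(b - std::sqrt(disc));
  if (cm < 0) cm = 0;
  if (cm > I1p_tot) cm = I1p_tot;
  if (cm > PP1_tot) cm = PP1_tot;
  *cmplx = cm;
  *pp1_free = PP1_tot - cm;
  *i1p_free = I1p_tot - cm;
}

// two-state PKA substrate phosphorylation balance
static inline double phos_rhs(double f, double C, double PP,
                              double kp, double kd) {
  return kp*C*(1.0 - f) - kd*PP*f;
}

// ---------------------------------------------------------------------------
// Signaling right-hand side (first BM_NSIG entries of y/dy)
// ---------------------------------------------------------------------------
static void sig_rhs(double t, const double* y, double* dy,
                    const double* p, const Ctx& cx) {
  (void)t;
  const double v[3] = { p[P_v_cav], p[P_v_ecav], p[P_v_cyt] };
  const double Rt_loc[3] = {
    p[P_Rb1_tot_cell]*p[P_Rb1_frac_cav]/v[0],
    p[P_Rb1_tot_cell]*p[P_Rb1_frac_ecav]/v[1],
    p[P_Rb1_tot_cell]*p[P_Rb1_frac_cyt]/v[2] };
  const double Gs_tot[3] = { p[P_Gs_tot_cav], p[P_Gs_tot_ecav], p[P_Gs_tot_cyt] };

  // cytosolic PP1 partition (I-1 steady-state approximation)
  double pp1f_cyt, cplx, i1pf;
  pp1_inhib1(y[S_I1p_tot_cyt], p[P_PP1_tot_cyt], p[P_K_Inhib1],
             &pp1f_cyt, &cplx, &i1pf);

  // effective phosphatase activities per compartment (Calyculin scaling)
  const double PPc[3] = {
    cx.pp_scale*(p[P_PP1_cav] + p[P_PP2A_cav]),
    cx.pp_scale*(p[P_PP1_ecav]),
    cx.pp_scale*(pp1f_cyt + p[P_PP2A_cyt]) };

  const double camp[3] = { y[S_cAMP_cav], y[S_cAMP_ecav], y[S_cAMP_cyt] };
  double dcamp[3];

  for (int i = 0; i < 3; ++i) {
    const double gsa  = y[S_GsaGTP_cav + i];
    const double gsad = y[S_GsaGDP_cav + i];
    const double gsbg = y[S_Gsbg_cav + i];
    const double rpka = y[S_Rpka_cav + i];
    const double rgrk = y[S_Rgrk_cav + i];
    double Rtnp = Rt_loc[i] - rpka - rgrk;
    if (Rtnp < 0) Rtnp = 0;
    double Gavail = Gs_tot[i] - gsa - gsad;
    if (Gavail < 0) Gavail = 0;

    RecEq eq = receptor_equilibrium(cx.iso, Rtnp, Gavail,
                                    p[P_K_b1_L], p[P_K_b1_H], p[P_K_b1_C]);

    // G-protein activation / hydrolysis / reassociation
    const double act = p[P_k_gs_act1]*eq.RG + p[P_k_gs_act2]*eq.LRG;
    const double reas = p[P_k_gs_reassoc]*gsad*gsbg;
    dy[S_GsaGTP_cav + i] = act - p[P_k_gs_hyd]*gsa;
    dy[S_GsaGDP_cav + i] = p[P_k_gs_hyd]*gsa - reas;
    dy[S_Gsbg_cav + i]   = act - reas;

    // PKA chain in compartment i
    const double Ktot = (i == 2 ? p[P_PKA_tot_cyt] :
                         (i == 0 ? p[P_PKA_tot_cav] : p[P_PKA_tot_ecav])) * cx.pka_scale;
    const double Kd2 = (i == 2 ? p[P_K_PKAI] : p[P_K_PKAII]);
    const double PKItot = (i == 0 ? p[P_PKI_tot_cav] :
                           (i == 1 ? p[P_PKI_tot_ecav] : p[P_PKI_tot_cyt]));
    const int o = 4*i; // offset for A2/A4/C/CPKI blocks
    const double A2 = y[S_A2_cav + o], A4 = y[S_A4_cav + o];
    const double C = y[S_C_cav + o], CPKI = y[S_CPKI_cav + o];
    double A0 = Ktot - 0.5*(C + CPKI) - A2 - A4;
    if (A0 < 0) A0 = 0;
    const double D = 0.5*(C + CPKI);
    const double c2 = camp[i]*camp[i];
    const double kon = p[P_k_pka_camp_on];
    const double r1 = kon*(A0*c2 - Kd2*Kd2*A2);
    const double r2 = kon*(A2*c2 - Kd2*Kd2*A4);
    const double kdb = p[P_k_pka_diss]/p[P_K_pka_diss];
    const double r3 = p[P_k_pka_diss]*A4 - kdb*D*C*C;
    double PKIfree = PKItot - CPKI; if (PKIfree < 0) PKIfree = 0;
    const double r4 = p[P_k_pki_on]*C*PKIfree - p[P_k_pki_off]*CPKI;
    dy[S_A2_cav + o] = r1 - r2;
    dy[S_A4_cav + o] = r2 - r3;
    dy[S_C_cav + o] = 2.0*r3 - r4;
    dy[S_CPKI_cav + o] = r4;

    // receptor desensitization: PKA acts on all non-phosphorylated receptor,
    // GRK2 only on ligand-bound states
    const double Csat = C/(p[P_Km_bar_pka] + C);
    dy[S_Rpka_cav + i] = p[P_k_bar_pka]*Csat*Rtnp - p[P_k_bar_pka_dp]*PPc[i]*rpka;
    dy[S_Rgrk_cav + i] = p[P_k_bar_grk]*(eq.LR + eq.LRG)
                         - p[P_k_bar_grk_dp]*PPc[i]*rgrk;

    // cAMP production / degradation
    double jac;
    if (i == 0)
      jac = ac_rate(gsa, gsbg, p[P_AC56_conc_cav], p[P_kcat_AC56],
                    p[P_ACb_frac_cav], p[P_K_AC56_gsa], p[P_h_AC_gsa],
                    p[P_s_AC56_gbg], p[P_K_AC56_gbg]);
    else if (i == 1)
      jac = ac_rate(gsa, gsbg, p[P_AC47_conc_ecav], p[P_kcat_AC47],
                    p[P_ACb_frac_ecav], p[P_K_AC47_gsa], p[P_h_AC_gsa],
                    p[P_s_AC47_gbg], p[P_K_AC47_gbg]);
    else
      jac = ac_rate(gsa, gsbg, p[P_AC47_conc_cyt], p[P_kcat_AC47],
                    p[P_ACb_frac_cyt], p[P_K_AC47_gsa], p[P_h_AC_gsa],
                    p[P_s_AC47_gbg], p[P_K_AC47_gbg]);

    double jpde;
    if (i == 0)
      jpde = pde_rate(camp[0], p[P_PDE2_cav], p[P_PDE3_cav], p[P_PDE4_cav],
                      y[S_fPDE3_cav], y[S_fPDE4_cav], p, cx);
    else if (i == 1)
      jpde = pde_rate(camp[1], p[P_PDE2_ecav], 0.0, p[P_PDE4_ecav],
                      0.0, y[S_fPDE4_ecav], p, cx);
    else
      jpde = pde_rate(camp[2], p[P_PDE2_cyt], p[P_PDE3_cyt], p[P_PDE4_cyt],
                      y[S_fPDE3_cyt], y[S_fPDE4_cyt], p, cx);

    // cAMP consumed/released by PKA binding (2 molecules per step)
    dcamp[i] = jac - jpde - 2.0*(r1 + r2);
  }

  // inter-compartment diffusion (amounts antisymmetric by construction)
  const double Fce = p[P_J_camp_cav_ecav]*(camp[0] - camp[1]);
  const double Fcc = p[P_J_camp_cav_cyt]*(camp[0] - camp[2]);
  const double Fec = p[P_J_camp_ecav_cyt]*(camp[1] - camp[2]);
  dcamp[0] += (-Fce - Fcc)/v[0];
  dcamp[1] += ( Fce - Fec)/v[1];
  dcamp[2] += ( Fcc + Fec)/v[2];
  dy[S_cAMP_cav] = dcamp[0];
  dy[S_cAMP_ecav] = dcamp[1];
  dy[S_cAMP_cyt] = dcamp[2];

  // PDE3/PDE4 phosphorylation states
  dy[S_fPDE3_cav] = phos_rhs(y[S_fPDE3_cav], y[S_C_cav], PPc[0],
                             p[P_k_pde_phos], p[P_k_pde_dephos]);
  dy[S_fPDE3_cyt] = phos_rhs(y[S_fPDE3_cyt], y[S_C_cyt], PPc[2],
                             p[P_k_pde_phos], p[P_k_pde_dephos]);
  dy[S_fPDE4_cav] = phos_rhs(y[S_fPDE4_cav], y[S_C_cav], PPc[0],
                             p[P_k_pde_phos], p[P_k_pde_dephos]);
  dy[S_fPDE4_ecav] = phos_rhs(y[S_fPDE4_ecav], y[S_C_ecav], PPc[1],
                              p[P_k_pde_phos], p[P_k_pde_dephos]);
  dy[S_fPDE4_cyt] = phos_rhs(y[S_fPDE4_cyt], y[S_C_cyt], PPc[2],
                             p[P_k_pde_phos], p[P_k_pde_dephos]);

  // inhibitor-1 (cytosol): phosphorylated by C, dephosphorylated by PP2A
  {
    double i1np = p[P_I1_tot_cyt] - y[S_I1p_tot_cyt];
    if (i1np < 0) i1np = 0;
    dy[S_I1p_tot_cyt] = p[P_k_i1_phos]*y[S_C_cyt]*i1np
      - p[P_k_i1_dephos]*cx.pp_scale*p[P_PP2A_cyt]*i1pf;
  }

  // scalar PKA substrate phosphorylation fractions
  const double Ccav = y[S_C_cav], Cecav = y[S_C_ecav], Ccyt = y[S_C_cyt];
  const double PPcav = PPc[0], PPecav = PPc[1];
  dy[S_fLTCC_cav]  = phos_rhs(y[S_fLTCC_cav], Ccav, PPcav,
                              p[P_kp_ltcc_cav], p[P_kd_ltcc_cav]);
  dy[S_fLTCC_ecav] = phos_rhs(y[S_fLTCC_ecav], Cecav, PPecav,
                              p[P_kp_ltcc_ecav], p[P_kd_ltcc_ecav]);
  dy[S_fRyR]  = phos_rhs(y[S_fRyR], Cecav, cx.pp_scale*p[P_PP1_ecav],
                         p[P_kp_ryr], p[P_kd_ryr]);
  dy[S_fINa]  = phos_rhs(y[S_fINa], Ccav, PPcav, p[P_kp_ina], p[P_kd_ina]);
  dy[S_fPLB]  = phos_rhs(y[S_fPLB], Ccyt, cx.pp_scale*pp1f_cyt,
                         p[P_kp_plb], p[P_kd_plb]);
  dy[S_fTnI]  = phos_rhs(y[S_fTnI], Ccyt, cx.pp_scale*p[P_PP2A_cyt],
                         p[P_kp_tni], p[P_kd_tni]);
  dy[S_fPLM]  = phos_rhs(y[S_fPLM], Ccav, PPcav, p[P_kp_plm], p[P_kd_plm]);
  dy[S_fIKur] = phos_rhs(y[S_fIKur], Cecav, cx.pp_scale*p[P_PP1_ecav],
                         p[P_kp_ikur], p[P_kd_ikur]);
  dy[S_fIKtof] = phos_rhs(y[S_fIKtof], Cecav, cx.pp_scale*p[P_PP1_ecav],
                          p[P_kp_iktof], p[P_kd_iktof]);
}

// ---------------------------------------------------------------------------
// L-type Ca channel Markov sub-model (9 + 9 states, one population)
// Chain: C1=C2=C3=C4=CP=O, O=I1 (Ca), O=I2 (V), I1=I3, I2=I3.
// Phosphorylated branch: activation rates evaluated at V + dVact_p, CP->O
// rate kcop (voltage-insensitive rate-limiting step), shared gamma.
// ---------------------------------------------------------------------------
static void ltcc_rates(double V, const double* p,
                       double* al, double* be) {
  const double e1 = std::exp((V + 12.0)/10.0);
  *al = p[P_ltcc_a0]*e1*
    (1.0 + 0.7*std::exp(-(V + 40.0)*(V + 40.0)/10.0)
         - 0.75*std::exp(-(V + 20.0)*(V + 20.0)/400.0)) /
    (1.0 + 0.12*e1);
  *be = p[P_ltcc_b0]*std::exp(-(V + 12.0)/13.0);
}

static void ltcc_rhs_block(const double* s, double* ds, double V, double Cass,
                           double kphos, double kdeph, const double* p) {
  double a, b, ap, bp;
  ltcc_rates(V, p, &a, &b);
  ltcc_rates(V + p[P_ltcc_dVact_p], p, &ap, &bp);
  const double cah = std::pow(Cass, p[P_ltcc_gamma_hill]);
  const double kh = std::pow(p[P_ltcc_Kpc_half], p[P_ltcc_gamma_hill]);
  const double gamma = p[P_ltcc_Kpc_max]*cah/(kh + cah);
  const double Kpcf = 13.0*(1.0 - std::exp(-(V + 14.5)*(V + 14.5)/100.0));
  const double kvi = p[P_ltcc_kvi];
  const double Kpcb = p[P_ltcc_Kpcb];

  // indices within the 18-long block
  enum {C1, C2, C3, C4, CP, O, I1, I2, I3};
  for (int ph = 0; ph < 2; ++ph) {
    const int off = 9*ph;
    const double A = ph ? ap : a, B = ph ? bp : b;
    const double kco = ph ? p[P_ltcc_kcop] : p[P_ltcc_kco];
    // deactivation through the pre-open state accelerates on
    // hyperpolarization (voltage-insensitive at test potentials)
    const double vfac = 1.0 + std::exp(-(V + p[P_ltcc_koc_Vh])/p[P_ltcc_koc_Vs]);
    const double koc = (ph ? p[P_ltcc_kocp] : p[P_ltcc_koc])*vfac;
    const double* x = s + off;
    double* dx = ds + off;
    const double f12 = 4*A*x[C1] - B*x[C2];
    const double f23 = 3*A*x[C2] - 2*B*x[C3];
    const double f34 = 2*A*x[C3] - 3*B*x[C4];
    const double f4p = A*x[C4] - 4*B*x[CP];
    const double fpo = kco*x[CP] - koc*x[O];
    const double foi1 = gamma*x[O] - Kpcb*x[I1];
    const double foi2 = kvi*Kpcf*x[O] - p[P_ltcc_kvr]*x[I2];
    const double fi13 = kvi*Kpcf*x[I1] - p[P_ltcc_kvr]*x[I3];
    const double fi23 = gamma*x[I2] - Kpcb*x[I3];
    dx[C1] = -f12;
    dx[C2] = f12 - f23;
    dx[C3] = f23 - f34;
    dx[C4] = f34 - f4p;
    dx[CP] = f4p - fpo;
    dx[O]  = fpo - foi1 - foi2;
    dx[I1] = foi1 - fi13;
    dx[I2] = foi2 - fi23;
    dx[I3] = fi13 + fi23;
  }
  // phosphorylation transitions (uniform over paired states)
  for (int k = 0; k < 9; ++k) {
    const double f = kphos*s[k] - kdeph*s[k + 9];
    ds[k] -= f;
    ds[k + 9] += f;
  }
}

// ---------------------------------------------------------------------------
// Fast Na channel Markov rates (lineage of the base-model/Clancy formulation;
// identical voltage dependence in both sub-diagrams)
// ---------------------------------------------------------------------------
struct NaRates {
  double a11, a12, a13, b11, b12, b13, a2, b2, a3, b3, a4, b4, a5, b5;
};
static NaRates na_rates(double V) {
  NaRates r;
  r.a11 = 3.802/(0.1027*std::exp(-(V + 2.5)/17.0) + 0.20*std::exp(-(V + 2.5)/150.0));
  r.a12 = 3.802/(0.1027*std::exp(-(V + 2.5)/15.0) + 0.23*std::exp(-(V + 2.5)/150.0));
  r.a13 = 3.802/(0.1027*std::exp(-(V + 2.5)/12.0) + 0.25*std::exp(-(V + 2.5)/150.0));
  r.b11 = 0.1917*std::exp(-(V + 2.5)/20.3);
  r.b12 = 0.20*std::exp(-(V - 2.5)/20.3);
  r.b13 = 0.22*std::exp(-(V - 7.5)/20.3);
  r.a3 = 7.0e-7*std::exp(-(V + 7.0)/7.7);
  r.b3 = 0.0084 + 0.00002*(V + 7.0);
  r.a2 = 1.0/(0.188495*std::exp(-(V + 7.0)/16.6) + 0.393956);
  r.b2 = r.a13*r.a2*r.a3/(r.b13*r.b3);
  r.a4 = r.a2/100.0; r.b4 = r.a3;
  r.a5 = r.a2/95000.0; r.b5 = r.a3/50.0;
  return r;
}

static void na_rhs_block(const double* s, double* ds, double V,
                         double kphos, double kdeph) {
  NaRates r = na_rates(V);
  enum {C3, C2, C1, O, IF, I1, I2, IC2, IC3};
  for (int ph = 0; ph < 2; ++ph) {
    const int off = 9*ph;
    const double* x = s + off;
    double* dx = ds + off;
    const double f32 = r.a11*x[C3] - r.b11*x[C2];
    const double f21 = r.a12*x[C2] - r.b12*x[C1];
    const double f1o = r.a13*x[C1] - r.b13*x[O];
    const double foif = r.a2*x[O] - r.b2*x[IF];
    const double fifc1 = r.a3*x[IF] - r.b3*x[C1];
    const double fic2c2 = r.a3*x[IC2] - r.b3*x[C2];
    const double fic3c3 = r.a3*x[IC3] - r.b3*x[C3];
    const double fif1 = r.a4*x[IF] - r.b4*x[I1];
    const double f12i = r.a5*x[I1] - r.b5*x[I2];
    const double fic32 = r.a11*x[IC3] - r.b11*x[IC2];
    const double fic2if = r.a12*x[IC2] - r.b12*x[IF];
    dx[C3] = -f32 + fic3c3;
    dx[C2] = f32 - f21 + fic2c2;
    dx[C1] = f21 - f1o + fifc1;
    dx[O]  = f1o - foif;
    dx[IF] = foif - fifc1 - fif1 + fic2if;
    dx[I1] = fif1 - f12i;
    dx[I2] = f12i;
    dx[IC2] = fic32 - fic2c2 - fic2if;
    dx[IC3] = -fic32 - fic3c3;
  }
  for (int k = 0; k < 9; ++k) {
    const double f = kphos*s[k] - kdeph*s[k + 9];
    ds[k] -= f;
    ds[k + 9] += f;
  }
}

// ---------------------------------------------------------------------------
// RyR Markov (4 + 4 states); forward Ca-dependent rates sped up when
// phosphorylated
// ---------------------------------------------------------------------------
static void ryr_rhs_block(const double* s, double* ds, double Cass,
                          double kphos, double kdeph, const double* p) {
  const double ca4 = std::pow(Cass, 4.0), ca3 = std::pow(Cass, 3.0);
  enum {C1, C2, O1, O2};
  for (int ph = 0; ph < 2; ++ph) {
    const int off = 4*ph;
    const double fs = ph ? p[P_ryr_fwd_scale] : 1.0;
    const double bs = ph ? p[P_ryr_bwd_scale] : 1.0;
    const double* x = s + off;
    double* dx = ds + off;
    const double f_c1o1 = fs*p[P_ryr_kap]*ca4*x[C1] - bs*p[P_ryr_kam]*x[O1];
    const double f_o1o2 = fs*p[P_ryr_kbp]*ca3*x[O1] - bs*p[P_ryr_kbm]*x[O2];
    const double f_o1c2 = p[P_ryr_kcp]*x[O1] - p[P_ryr_kcm]*x[C2];
    dx[C1] = -f_c1o1;
    dx[O1] = f_c1o1 - f_o1o2 - f_o1c2;
    dx[O2] = f_o1o2;
    dx[C2] = f_o1c2;
  }
  for (int k = 0; k < 4; ++k) {
    const double f = kphos*s[k] - kdeph*s[k + 4];
    ds[k] -= f;
    ds[k + 4] += f;
  }
}

// ---------------------------------------------------------------------------
// Full-cell right-hand side (signaling + electrophysiology)
// y has BM_NSIG + BM_NCELL entries; cur (if non-null) receives BM_NCUR values.
// ---------------------------------------------------------------------------
static void cell_rhs(double t, const double* y, double* dy,
                     const double* p, const Ctx& cx, double* cur) {
  sig_rhs(t, y, dy, p, cx);
  const double* e = y + BM_NSIG;
  double* de = dy + BM_NSIG;
  for (int k = 0; k < BM_NCELL; ++k) de[k] = 0.0;

  const double V = cx.clamp ? cx.clamp_V : e[E_V];
  const double Cai = e[E_Cai], Cass = e[E_Cass];
  const double CaJSR = e[E_CaJSR], CaNSR = e[E_CaNSR];
  const double Nai = e[E_Nai], Ki = e[E_Ki];
  const double RTF = p[P_Rgas]*p[P_TempK]/p[P_Farad];

  // reversal potentials
  const double EK = RTF*std::log(p[P_Ko]/Ki);
  const double ENa = RTF*std::log((0.9*p[P_Nao] + 0.1*p[P_Ko])/(0.9*Nai + 0.1*Ki));
  const double ECaN = 0.5*RTF*std::log(p[P_Cao]/Cai);

  // phosphatase context (same as signaling module)
  double pp1f_cyt, cplx, i1pf;
  pp1_inhib1(y[S_I1p_tot_cyt], p[P_PP1_tot_cyt], p[P_K_Inhib1],
             &pp1f_cyt, &cplx, &i1pf);
  const double PPcav = cx.pp_scale*(p[P_PP1_cav] + p[P_PP2A_cav]);
  const double PPecav = cx.pp_scale*p[P_PP1_ecav];

  // ---- Markov channels ----
  ltcc_rhs_block(e + E_lcav_C1, de + E_lcav_C1, V, Cass,
                 p[P_kp_ltcc_cav]*y[S_C_cav], p[P_kd_ltcc_cav]*PPcav, p);
  ltcc_rhs_block(e + E_lecav_C1, de + E_lecav_C1, V, Cass,
                 p[P_kp_ltcc_ecav]*y[S_C_ecav], p[P_kd_ltcc_ecav]*PPecav, p);
  na_rhs_block(e + E_na_C3, de + E_na_C3, V,
               p[P_kp_ina]*y[S_C_cav], p[P_kd_ina]*PPcav);
  ryr_rhs_block(e + E_ryr_C1, de + E_ryr_C1, Cass,
                p[P_kp_ryr]*y[S_C_ecav], p[P_kd_ryr]*PPecav, p);

  // ---- currents ----
  const double fcav = p[P_ltcc_frac_cav];
  const double gp = p[P_G_CaLp_factor];
  double ICaL_cav = p[P_G_CaL]*fcav*
    (e[E_lcav_O] + gp*e[E_lcav_Op])*(V - p[P_E_CaL]);
  double ICaL_ecav = p[P_G_CaL]*(1.0 - fcav)*
    (e[E_lecav_O] + gp*e[E_lecav_Op])*(V - p[P_E_CaL]);
  if (cx.block_cav) ICaL_cav = 0.0;
  if (cx.block_ecav) ICaL_ecav = 0.0;
  const double ICaL = ICaL_cav + ICaL_ecav;

  const double INa = p[P_G_Na]*
    (e[E_na_O] + p[P_G_Nap_factor]*e[E_na_Op])*(V - ENa);

  // IKto,f: two gate sets (control + phosphorylated kinetics), mixed by fIKtof
  {
    const double aa = 0.18064*std::exp(0.03577*(V + 30.0));
    const double ba = 0.3956*std::exp(-0.06237*(V + 30.0));
    const double ai = (0.000152*std::exp(-(V + 13.5)/7.0)) /
                      (0.0067083*std::exp(-(V + 33.5)/7.0) + 1.0);
    const double bi = (0.00095*std::exp((V + 33.5)/7.0)) /
                      (0.051335*std::exp((V + 33.5)/7.0) + 1.0);
    de[E_ato_f] = aa*(1.0 - e[E_ato_f]) - ba*e[E_ato_f];
    de[E_ito_f] = ai*(1.0 - e[E_ito_f]) - bi*e[E_ito_f];
    const double Vp = V - p[P_iktof_shift_act];
    const double Vq = V - p[P_iktof_shift_inact];
    const double aap = 0.18064*std::exp(0.03577*(Vp + 30.0));
    const double bap = 0.3956*std::exp(-0.06237*(Vp + 30.0));
    const double aip = (0.000152*std::exp(-(Vq + 13.5)/7.0)) /
                       (0.0067083*std::exp(-(Vq + 33.5)/7.0) + 1.0);
    const double bip = (0.00095*std::exp((Vq + 33.5)/7.0)) /
                       (0.051335*std::exp((Vq + 33.5)/7.0) + 1.0);
    de[E_atop_f] = aap*(1.0 - e[E_atop_f]) - bap*e[E_atop_f];
    de[E_itop_f] = aip*(1.0 - e[E_itop_f]) - bip*e[E_itop_f];
  }
  const double fkto = y[S_fIKtof];
  const double IKtof = p[P_G_Ktof]*(V - EK)*
    ((1.0 - fkto)*std::pow(e[E_ato_f], 3.0)*e[E_ito_f] +
     fkto*p[P_gktof_p_factor]*std::pow(e[E_atop_f], 3.0)*e[E_itop_f]);

  // IKur and IKss
  {
    const double ass = 1.0/(1.0 + std::exp(-(V + 22.5)/7.7));
    const double iss = 1.0/(1.0 + std::exp((V + 45.2)/5.7));
    const double tau_aur = 0.493*std::exp(-0.0629*V) + 2.058;
    const double tau_iur = 1200.0 - 170.0/(1.0 + std::exp((V + 45.2)/5.7));
    de[E_aur] = (ass - e[E_aur])/tau_aur;
    de[E_iur] = (iss - e[E_iur])/tau_iur;
    const double tau_kss = 39.3*std::exp(-0.0862*V) + 13.17;
    de[E_aKss] = (ass - e[E_aKss])/tau_kss;
  }
  const double IKur = p[P_G_Kur]*(1.0 + p[P_gkur_p_gain]*y[S_fIKur])*
    e[E_aur]*e[E_iur]*(V - EK);
  const double IKss = p[P_G_Kss]*e[E_aKss]*(V - EK);

  // IKr (5-state Markov)
  {
    const double a0 = 0.022348*std::exp(0.01176*V);
    const double b0 = 0.047002*std::exp(-0.0631*V);
    const double a1 = 0.013733*std::exp(0.038198*V);
    const double b1 = 6.89e-5*std::exp(-0.04178*V);
    const double ai = 0.090821*std::exp(0.023391*(V + 5.0));
    const double bi = 0.006497*std::exp(-0.03268*(V + 5.0));
    const double f01 = a0*e[E_kr_C0] - b0*e[E_kr_C1];
    const double f12 = p[P_ikr_kf]*e[E_kr_C1] - p[P_ikr_kb]*e[E_kr_C2];
    const double f2o = a1*e[E_kr_C2] - b1*e[E_kr_O];
    const double foi = ai*e[E_kr_O] - bi*e[E_kr_I];
    de[E_kr_C0] = -f01;
    de[E_kr_C1] = f01 - f12;
    de[E_kr_C2] = f12 - f2o;
    de[E_kr_O] = f2o - foi;
    de[E_kr_I] = foi;
  }
  const double EKr = RTF*std::log((0.98*p[P_Ko] + 0.02*p[P_Nao]) /
                                  (0.98*Ki + 0.02*Nai));
  const double IKr = p[P_G_Kr]*e[E_kr_O]*(V - EKr);

  const double IK1 = p[P_ik1_gmax]*(p[P_Ko]/(p[P_Ko] + p[P_ik1_km_ko]))*
    (V - EK)/(1.0 + std::exp(0.0896*(V - EK)));

  const double OClCa = 0.2/(1.0 + std::exp(-(V - 46.7)/7.8));
  const double IClCa = p[P_G_ClCa]*OClCa*(Cai/(Cai + p[P_Km_Cl]))*(V - p[P_E_Cl]);

  // Na/K pump with phospholemman modulation of Km,Nai
  const double sigma = (std::exp(p[P_Nao]/67300.0) - 1.0)/7.0;
  const double fNaK = 1.0/(1.0 + 0.1245*std::exp(-0.1*V/RTF) +
                           0.0365*sigma*std::exp(-V/RTF));
  const double KmNai_eff = p[P_Km_Nai]*(1.0 - p[P_plm_km_red]*y[S_fPLM]);
  const double INaK = p[P_I_NaK_max]*fNaK*
    (1.0/(1.0 + std::pow(KmNai_eff/Nai, 1.5)))*
    (p[P_Ko]/(p[P_Ko] + p[P_Km_Ko_nak]));

  // Na/Ca exchanger
  const double VFRT = V/RTF;
  const double INaCa = p[P_k_NaCa]*
    (1.0/(std::pow(p[P_Km_Na_ncx], 3.0) + std::pow(p[P_Nao], 3.0)))*
    (1.0/(p[P_Km_Ca_ncx] + p[P_Cao]))*
    (1.0/(1.0 + p[P_ksat_ncx]*std::exp((p[P_eta_ncx] - 1.0)*VFRT)))*
    (std::exp(p[P_eta_ncx]*VFRT)*Nai*Nai*Nai*p[P_Cao] -
     std::exp((p[P_eta_ncx] - 1.0)*VFRT)*std::pow(p[P_Nao], 3.0)*Cai);

  const double IpCa = p[P_I_pCa_max]*Cai*Cai/(Cai*Cai + p[P_Km_pCa]*p[P_Km_pCa]);
  const double ICab = p[P_G_Cab]*(V - ECaN);
  const double INab = p[P_G_Nab]*(V - ENa);

  // stimulus
  double Istim = 0.0;
  if (cx.pacing && !cx.clamp) {
    const double tt = t - cx.stim_t0;
    if (tt >= 0) {
      const double ph = tt - std::floor(tt/cx.stim_period)*cx.stim_period;
      if (ph < p[P_stim_dur]) Istim = p[P_stim_amp];
    }
  }

  // ---- Ca handling ----
  const double Po_ryr = e[E_ryr_O1] + e[E_ryr_O2] + e[E_ryr_O1p] + e[E_ryr_O2p];
  double Jrel = p[P_nu1_rel]*Po_ryr*(CaJSR - Cass)*e[E_PRyR];
  if (cx.no_cicr) Jrel = 0.0;
  const double Jtr = (CaNSR - CaJSR)/p[P_tau_tr];
  const double Jxfer = (Cass - Cai)/p[P_tau_xfer];
  const double Jleak = p[P_nu2_leak]*(CaNSR - Cai);
  const double Km_up_eff = p[P_Km_up]*(1.0 - p[P_plb_km_red]*y[S_fPLB]);
  const double Jup = p[P_v_up]*Cai*Cai/(Cai*Cai + Km_up_eff*Km_up_eff);

  // troponin: phosphorylated TnI increases Ca unbinding
  const double koff_l = p[P_k_ltrpn_m]*(1.0 + p[P_tni_koff_gain]*y[S_fTnI]);
  const double koff_h = p[P_k_htrpn_m]*(1.0 + p[P_tni_koff_gain]*y[S_fTnI]);
  const double dLT = p[P_k_ltrpn_p]*Cai*(p[P_LTRPN_tot] - e[E_LTRPNCa]) -
                     koff_l*e[E_LTRPNCa];
  const double dHT = p[P_k_htrpn_p]*Cai*(p[P_HTRPN_tot] - e[E_HTRPNCa]) -
                     koff_h*e[E_HTRPNCa];
  de[E_LTRPNCa] = dLT;
  de[E_HTRPNCa] = dHT;
  const double Jtrpn = dLT + dHT;

  de[E_PRyR] = -p[P_pryr_decay]*e[E_PRyR] -
    p[P_pryr_drive]*(ICaL/p[P_ICaL_max_norm])*
    std::exp(-(V - 5.0)*(V - 5.0)/648.0);

  const double conv_myo = p[P_Acap]*p[P_Cm]/(2.0*p[P_V_myo]*p[P_Farad]);
  const double conv_ss = p[P_Acap]*p[P_Cm]/(2.0*p[P_V_ss]*p[P_Farad]);
  const double Bi = 1.0/(1.0 + p[P_CMDN_tot]*p[P_Km_CMDN] /
                         std::pow(p[P_Km_CMDN] + Cai, 2.0));
  const double Bss = 1.0/(1.0 + p[P_CMDN_tot]*p[P_Km_CMDN] /
                          std::pow(p[P_Km_CMDN] + Cass, 2.0));
  const double Bjsr = 1.0/(1.0 + p[P_CSQN_tot]*p[P_Km_CSQN] /
                           std::pow(p[P_Km_CSQN] + CaJSR, 2.0));

  de[E_Cai] = Bi*(Jleak + Jxfer - Jup - Jtrpn -
                  (ICab - 2.0*INaCa + IpCa)*conv_myo);
  de[E_Cass] = Bss*(Jrel*p[P_V_jsr]/p[P_V_ss] - Jxfer*p[P_V_myo]/p[P_V_ss] -
                    ICaL*conv_ss);
  de[E_CaJSR] = Bjsr*(Jtr - Jrel);
  de[E_CaNSR] = (Jup - Jleak)*p[P_V_myo]/p[P_V_nsr] - Jtr*p[P_V_jsr]/p[P_V_nsr];

  const double conv_ion = p[P_Acap]*p[P_Cm]/(p[P_V_myo]*p[P_Farad]);
  de[E_Nai] = -(INa + INab + 3.0*INaCa + 3.0*INaK)*conv_ion;
  // stimulus excluded from K+ bookkeeping (documented convention)
  de[E_Ki] = -(IKtof + IK1 + IKss + IKur + IKr - 2.0*INaK)*conv_ion;

  const double Itot = ICaL + IpCa + INaCa + ICab + INa + INab + INaK +
                      IKtof + IK1 + IKur + IKss + IKr + IClCa;
  de[E_V] = cx.clamp ? 0.0 : -(Itot - Istim);

  if (cur) {
    cur[CUR_ICaL] = ICaL; cur[CUR_ICaL_cav] = ICaL_cav;
    cur[CUR_ICaL_ecav] = ICaL_ecav;
    cur[CUR_IpCa] = IpCa; cur[CUR_INaCa] = INaCa; cur[CUR_ICab] = ICab;
    cur[CUR_INa] = INa; cur[CUR_INab] = INab; cur[CUR_INaK] = INaK;
    cur[CUR_IKtof] = IKtof; cur[CUR_IK1] = IK1; cur[CUR_IKur] = IKur;
    cur[CUR_IKss] = IKss; cur[CUR_IKr] = IKr; cur[CUR_IClCa] = IClCa;
    cur[CUR_Istim] = Istim;
    cur[CUR_Jrel] = Jrel; cur[CUR_Jup] = Jup; cur[CUR_Jleak] = Jleak;
    cur[CUR_Jtr] = Jtr; cur[CUR_Jxfer] = Jxfer;
  }
}

// dispatcher
static void model_rhs(int mode, double t, const double* y, double* dy,
                      const double* p, const Ctx& cx, double* cur) {
  if (mode == 0) sig_rhs(t, y, dy, p, cx);
  else cell_rhs(t, y, dy, p, cx, cur);
}

// occupancy renormalization after accepted steps; returns number of rescues
static int renormalize(int mode, double* y) {
  if (mode == 0) return 0;
  int n = 0;
  double* e = y + BM_NSIG;
  struct Blk { int off, len; };
  const Blk blocks[] = { {E_ryr_C1, 8}, {E_lcav_C1, 18}, {E_lecav_C1, 18},
                         {E_na_C3, 18}, {E_kr_C0, 5} };
  for (const Blk& b : blocks) {
    double s = 0;
    for (int k = 0; k < b.len; ++k) s += e[b.off + k];
    if (std::fabs(s - 1.0) > 1e-8 && s > 0) {
      for (int k = 0; k < b.len; ++k) e[b.off + k] /= s;
      ++n;
    }
  }
  return n;
}

// ---------------------------------------------------------------------------
// Integrators
// ---------------------------------------------------------------------------
struct SimResult {
  std::vector<double> times;
  std::vector<double> states;   // row-major, one row per record time
  std::vector<double> currents; // row-major (full mode only)
  long n_steps;
  int n_renorm;
};

// Cash-Karp 4(5) embedded pair, one adaptive attempt
static double ck_step(int mode, double t, double* y, double dt, int n,
                      const double* p, const Ctx& cx,
                      std::vector<double>& work) {
  static const double b21 = 1.0/5.0;
  static const double b31 = 3.0/40.0, b32 = 9.0/40.0;
  static const double b41 = 3.0/10.0, b42 = -9.0/10.0, b43 = 6.0/5.0;
  static const double b51 = -11.0/54.0, b52 = 5.0/2.0, b53 = -70.0/27.0,
                      b54 = 35.0/27.0;
  static const double b61 = 1631.0/55296.0, b62 = 175.0/512.0,
                      b63 = 575.0/13824.0, b64 = 44275.0/110592.0,
                      b65 = 253.0/4096.0;
  static const double c1 = 37.0/378.0, c3 = 250.0/621.0, c4 = 125.0/594.0,
                      c6 = 512.0/1771.0;
  static const double d1 = c1 - 2825.0/27648.0, d3 = c3 - 18575.0/48384.0,
                      d4 = c4 - 13525.0/55296.0, d5 = -277.0/14336.0,
                      d6 = c6 - 0.25;
  work.resize(8*n);
  double* k1 = work.data();
  double* k2 = k1 + n; double* k3 = k2 + n; double* k4 = k3 + n;
  double* k5 = k4 + n; double* k6 = k5 + n;
  double* yt = k6 + n; double* err = yt + n;

  model_rhs(mode, t, y, k1, p, cx, nullptr);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + dt*b21*k1[i];
  model_rhs(mode, t + 0.2*dt, yt, k2, p, cx, nullptr);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + dt*(b31*k1[i] + b32*k2[i]);
  model_rhs(mode, t + 0.3*dt, yt, k3, p, cx, nullptr);
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + dt*(b41*k1[i] + b42*k2[i] + b43*k3[i]);
  model_rhs(mode, t + 0.6*dt, yt, k4, p, cx, nullptr);
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + dt*(b51*k1[i] + b52*k2[i] + b53*k3[i] + b54*k4[i]);
  model_rhs(mode, t + dt, yt, k5, p, cx, nullptr);
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + dt*(b61*k1[i] + b62*k2[i] + b63*k3[i] + b64*k4[i] + b65*k5[i]);
  model_rhs(mode, t + 0.875*dt, yt, k6, p, cx, nullptr);
  for (int i = 0; i < n; ++i) {
    const double dyi = dt*(c1*k1[i] + c3*k3[i] + c4*k4[i] + c6*k6[i]);
    err[i] = dt*(d1*k1[i] + d3*k3[i] + d4*k4[i] + d5*k5[i] + d6*k6[i]);
    yt[i] = y[i] + dyi;
  }
  // error norm (returned); caller decides acceptance
  double emax = 0.0;
  for (int i = 0; i < n; ++i) {
    const double sc = 1e-8 + std::max(std::fabs(y[i]), std::fabs(yt[i]));
    const double ei = std::fabs(err[i])/sc;
    if (ei > emax) emax = ei;
  }
  // tentatively copy the candidate into y (caller restores on reject)
  for (int i = 0; i < n; ++i) y[i] = yt[i];
  return emax;
}

static void rk4_step(int mode, double t, double* y, double dt, int n,
                     const double* p, const Ctx& cx,
                     std::vector<double>& work) {
  work.resize(5*n);
  double* k1 = work.data();
  double* k2 = k1 + n; double* k3 = k2 + n; double* k4 = k3 + n;
  double* yt = k4 + n;
  model_rhs(mode, t, y, k1, p, cx, nullptr);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5*dt*k1[i];
  model_rhs(mode, t + 0.5*dt, yt, k2, p, cx, nullptr);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5*dt*k2[i];
  model_rhs(mode, t + 0.5*dt, yt, k3, p, cx, nullptr);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + dt*k3[i];
  model_rhs(mode, t + dt, yt, k4, p, cx, nullptr);
  for (int i = 0; i < n; ++i)
    y[i] += dt/6.0*(k1[i] + 2.0*k2[i] + 2.0*k3[i] + k4[i]);
}

// next protocol discontinuity strictly after t (stimulus edges)
static double next_edge(double t, const Ctx& cx, const double* p) {
  if (!cx.pacing || cx.clamp) return R_PosInf;
  const double per = cx.stim_period, dur = p[P_stim_dur];
  double tt = t - cx.stim_t0;
  double base = std::floor(tt/per)*per;
  double cand[3] = { base + dur, base + per, base + per + dur };
  for (double c : cand)
    if (c > tt + 1e-12) return c + cx.stim_t0;
  return R_PosInf;
}

// [[Rcpp::export]]
List bm_simulate_cpp(NumericVector y0, NumericVector params,
                     double t0, double t1, double record_dt, List ctx_list,
                     std::string engine, double rtol, double dt_fixed,
                     double max_dt, int mode, bool record_currents,
                     double dt_fine, double dt_mid, double fine_window) {
  const Ctx cx = ctx_from_list(ctx_list);
  const double* p = REAL(params);
  const int n = (mode == 0) ? BM_NSIG : BM_NSIG + BM_NCELL;
  if (y0.size() != n) stop("state vector has wrong length");
  if ((int)params.size() != BM_NPAR) stop("parameter vector has wrong length");

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> work, ysave(n);
  SimResult res;
  res.n_steps = 0; res.n_renorm = 0;

  const int nrec = (int)std::floor((t1 - t0)/record_dt + 1e-9) + 1;
  res.times.reserve(nrec);
  res.states.reserve((size_t)nrec*n);
  const bool rc = record_currents && mode == 1;
  if (rc) res.currents.reserve((size_t)nrec*BM_NCUR);
  std::vector<double> cur(BM_NCUR);

  auto record = [&](double t) {
    res.times.push_back(t);
    res.states.insert(res.states.end(), y.begin(), y.end());
    if (rc) {
      std::vector<double> dyt(n);
      cell_rhs(t, y.data(), dyt.data(), p, cx, cur.data());
      res.currents.insert(res.currents.end(), cur.begin(), cur.end());
    }
  };

  double t = t0;
  record(t);
  double dt = (engine == "adaptive") ? std::min(record_dt, max_dt) : dt_fixed;

  for (int ir = 1; ir < nrec; ++ir) {
    const double t_target = t0 + ir*record_dt;
    while (t < t_target - 1e-9) {
      if (res.n_steps > 400000000L) stop("step budget exceeded");
      double edge = next_edge(t, cx, p);
      if (engine == "adaptive") {
        double h = std::min(dt, max_dt);
        h = std::min(h, t_target - t);
        if (edge - t > 1e-12) h = std::min(h, edge - t);
        std::copy(y.begin(), y.end(), ysave.begin());
        double err = ck_step(mode, t, y.data(), h, n, p, cx, work)/rtol;
        ++res.n_steps;
        bool bad = !std::isfinite(err);
        if (!bad)
          for (int i = 0; i < n; ++i)
            if (!std::isfinite(y[i])) { bad = true; break; }
        if (bad) {
          std::copy(ysave.begin(), ysave.end(), y.begin());
          dt = h*0.1;
          if (dt < 1e-10) stop("integration failed (non-finite state) at t=" +
                               std::to_string(t));
          continue;
        }
        if (err <= 1.0) {
          t += h;
          res.n_renorm += renormalize(mode, y.data());
          double fac = (err > 1e-12) ? 0.9*std::pow(err, -0.2) : 5.0;
          if (fac > 5.0) fac = 5.0;
          dt = h*fac;
        } else {
          std::copy(ysave.begin(), ysave.end(), y.begin());
          double fac = 0.9*std::pow(err, -0.25);
          if (fac < 0.1) fac = 0.1;
          dt = h*fac;
          if (dt < 1e-10) stop("step size underflow at t=" + std::to_string(t));
        }
      } else { // fixed-step RK4, optionally with the reference step policy
        double h = dt_fixed;
        if (dt_fine > 0 && cx.pacing && !cx.clamp) {
          // fine step inside the window after each stimulus onset
          const double tt = t - cx.stim_t0;
          if (tt >= -1e-12) {
            const double ph = tt - std::floor(tt/cx.stim_period)*cx.stim_period;
            h = (ph < fine_window) ? dt_fine : dt_mid;
          }
        }
        h = std::min(h, t_target - t);
        if (edge - t > 1e-12) h = std::min(h, edge - t);
        rk4_step(mode, t, y.data(), h, n, p, cx, work);
        ++res.n_steps;
        t += h;
        res.n_renorm += renormalize(mode, y.data());
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(y[i]))
            stop("integration failed (non-finite state) at t=" +
                 std::to_string(t));
      }
    }
    t = t_target;
    record(t);
  }

  const int nt = (int)res.times.size();
  NumericMatrix S(nt, n);
  for (int r = 0; r < nt; ++r)
    for (int i = 0; i < n; ++i) S(r, i) = res.states[(size_t)r*n + i];
  List out = List::create(
    _["time"] = NumericVector(res.times.begin(), res.times.end()),
    _["states"] = S,
    _["n_steps"] = (double)res.n_steps,
    _["n_renorm"] = res.n_renorm);
  if (rc) {
    NumericMatrix C(nt, BM_NCUR);
    for (int r = 0; r < nt; ++r)
      for (int i = 0; i < BM_NCUR; ++i)
        C(r, i) = res.currents[(size_t)r*BM_NCUR + i];
    out["currents"] = C;
  }
  return out;
}

// single RHS evaluation (for tests and conservation checks)
// [[Rcpp::export]]
NumericVector bm_rhs_cpp(NumericVector y, NumericVector params, double t,
                         List ctx_list, int mode) {
  const Ctx cx = ctx_from_list(ctx_list);
  const int n = (mode == 0) ? BM_NSIG : BM_NSIG + BM_NCELL;
  if (y.size() != n) stop("state vector has wrong length");
  NumericVector dy(n);
  model_rhs(mode, t, REAL(y), REAL(dy), REAL(params), cx, nullptr);
  return dy;
}

// currents and fluxes at a state
// [[Rcpp::export]]
NumericVector bm_currents_cpp(NumericVector y, NumericVector params, double t,
                              List ctx_list) {
  const Ctx cx = ctx_from_list(ctx_list);
  NumericVector dy(BM_NSIG + BM_NCELL), cur(BM_NCUR);
  cell_rhs(t, REAL(y), REAL(dy), REAL(params), cx, REAL(cur));
  cur.attr("names") = CharacterVector(BM_CNAMES, BM_CNAMES + BM_NCUR);
  return cur;
}

// receptor equilibrium (exported for unit tests / oracles)
// [[Rcpp::export]]
NumericVector bm_receptor_equilibrium_cpp(double L, double Rt, double Gt,
                                          double KL, double KH, double KC) {
  if (L < 0 || Rt < 0 || Gt < 0) stop("negative input");
  if (KL <= 0 || KH <= 0 || KC <= 0) stop("dissociation constants must be > 0");
  RecEq eq = receptor_equilibrium(L, Rt, Gt, KL, KH, KC);
  return NumericVector::create(_["R"] = eq.R, _["Gs"] = eq.G,
                               _["LR"] = eq.LR, _["LRG"] = eq.LRG,
                               _["RG"] = eq.RG);
}

// Markov generator matrices at clamped conditions (for null-space oracles)
// [[Rcpp::export]]
NumericMatrix bm_ltcc_generator_cpp(double V, double Cass, double kphos,
                                    double kdeph, NumericVector params) {
  const double* p = REAL(params);
  NumericMatrix G(18, 18);
  std::vector<double> s(18, 0.0), ds(18);
  for (int j = 0; j < 18; ++j) {
    std::fill(s.begin(), s.end(), 0.0);
    s[j] = 1.0;
    ltcc_rhs_block(s.data(), ds.data(), V, Cass, kphos, kdeph, p);
    for (int i = 0; i < 18; ++i) G(i, j) = ds[i];
  }
  return G;
}

// [[Rcpp::export]]
NumericMatrix bm_na_generator_cpp(double V, double kphos, double kdeph) {
  NumericMatrix G(18, 18);
  std::vector<double> s(18, 0.0), ds(18);
  for (int j = 0; j < 18; ++j) {
    std::fill(s.begin(), s.end(), 0.0);
    s[j] = 1.0;
    na_rhs_block(s.data(), ds.data(), V, kphos, kdeph);
    for (int i = 0; i < 18; ++i) G(i, j) = ds[i];
  }
  return G;
}

// [[Rcpp::export]]
NumericMatrix bm_ryr_generator_cpp(double Cass, double kphos, double kdeph,
                                   NumericVector params) {
  const double* p = REAL(params);
  NumericMatrix G(8, 8);
  std::vector<double> s(8, 0.0), ds(8);
  for (int j = 0; j < 8; ++j) {
    std::fill(s.begin(), s.end(), 0.0);
    s[j] = 1.0;
    ryr_rhs_block(s.data(), ds.data(), Cass, kphos, kdeph, p);
    for (int i = 0; i < 8; ++i) G(i, j) = ds[i];
  }
  return G;
}

// registries for R
// [[Rcpp::export]]
CharacterVector bm_param_names_cpp() {
  return CharacterVector(BM_PNAMES, BM_PNAMES + BM_NPAR);
}
// [[Rcpp::export]]
CharacterVector bm_sig_state_names_cpp() {
  return CharacterVector(BM_SNAMES, BM_SNAMES + BM_NSIG);
}
// [[Rcpp::export]]
CharacterVector bm_cell_state_names_cpp() {
  return CharacterVector(BM_ENAMES, BM_ENAMES + BM_NCELL);
}
// [[Rcpp::export]]
CharacterVector bm_current_names_cpp() {
  return CharacterVector(BM_CNAMES, BM_CNAMES + BM_NCUR);
}
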