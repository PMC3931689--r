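// Parameter and state registries for the compartmentalized beta1-adrenergic
// mouse ventricular myocyte model. Order defines the index contract with R:
// R builds the parameter vector from the ledger in exactly this order.
#ifndef BETAMYO_MODEL_DEF_H
#define BETAMYO_MODEL_DEF_H

// ---------------------------------------------------------------------------
// Parameters. Units: time ms, concentration uM, voltage mV, current pA/pF,
// volume uL, capacitance uF.
// ---------------------------------------------------------------------------
#define BM_PARAMS(X) \
  /* compartment volume fractions of V_cell (signaling) */ \
  X(v_cav) X(v_ecav) X(v_cyt) \
  /* beta1-AR receptor module */ \
  X(Rb1_tot_cell) X(Rb1_frac_cav) X(Rb1_frac_ecav) X(Rb1_frac_cyt) \
  X(K_b1_L) X(K_b1_H) X(K_b1_C) \
  X(Gs_tot_cav) X(Gs_tot_ecav) X(Gs_tot_cyt) \
  X(k_gs_act1) X(k_gs_act2) X(k_gs_hyd) X(k_gs_reassoc) \
  X(k_bar_pka) X(k_bar_pka_dp) X(k_bar_grk) X(k_bar_grk_dp) X(Km_bar_pka) \
  /* adenylyl cyclase module */ \
  X(AC_tot_cell) X(AC56_frac) \
  X(AC56_conc_cav) X(AC47_conc_ecav) X(AC47_conc_cyt) \
  X(kcat_AC56) X(kcat_AC47) \
  X(ACb_frac_cav) X(ACb_frac_ecav) X(ACb_frac_cyt) \
  X(K_AC56_gsa) X(K_AC47_gsa) X(h_AC_gsa) \
  X(s_AC56_gbg) X(K_AC56_gbg) X(s_AC47_gbg) X(K_AC47_gbg) \
  /* phosphodiesterase module */ \
  X(kcat_PDE2) X(kcat_PDE3) X(kcat_PDE4) \
  X(Km_PDE2) X(Km_PDE3) X(Km_PDE4) \
  X(PDE2_cav) X(PDE2_ecav) X(PDE2_cyt) \
  X(PDE3_cav) X(PDE3_cyt) \
  X(PDE4_cav) X(PDE4_ecav) X(PDE4_cyt) \
  X(delta_PDE3_phos) X(delta_PDE4_phos) \
  X(k_pde_phos) X(k_pde_dephos) \
  /* cAMP-PKA module */ \
  X(PKA_tot_cav) X(PKA_tot_ecav) X(PKA_tot_cyt) \
  X(K_PKAII) X(K_PKAI) \
  X(k_pka_camp_on) X(k_pka_diss) X(K_pka_diss) \
  X(PKI_tot_cav) X(PKI_tot_ecav) X(PKI_tot_cyt) \
  X(k_pki_on) X(k_pki_off) \
  /* phosphatases / inhibitor-1 */ \
  X(PP1_cav) X(PP2A_cav) X(PP1_ecav) X(PP1_tot_cyt) X(PP2A_cyt) \
  X(K_Inhib1) X(I1_tot_cyt) X(k_i1_phos) X(k_i1_dephos) \
  /* inter-compartment cAMP exchange (amount per ms per uM gradient, V_cell units) */ \
  X(J_camp_cav_ecav) X(J_camp_cav_cyt) X(J_camp_ecav_cyt) \
  /* PKA substrate phosphorylation kinetics (forward per uM C, back per uM PP) */ \
  X(kp_ltcc_cav) X(kd_ltcc_cav) X(kp_ltcc_ecav) X(kd_ltcc_ecav) \
  X(kp_ryr) X(kd_ryr) X(kp_ina) X(kd_ina) \
  X(kp_plb) X(kd_plb) X(kp_tni) X(kd_tni) X(kp_plm) X(kd_plm) \
  X(kp_ikur) X(kd_ikur) X(kp_iktof) X(kd_iktof) \
  /* cell geometry & physical constants */ \
  X(Acap) X(Cm) X(V_myo) X(V_ss) X(V_jsr) X(V_nsr) X(Farad) X(TempK) X(Rgas) \
  X(Ko) X(Nao) X(Cao) \
  /* Ca buffers */ \
  X(LTRPN_tot) X(HTRPN_tot) X(k_htrpn_p) X(k_htrpn_m) X(k_ltrpn_p) X(k_ltrpn_m) \
  X(CMDN_tot) X(Km_CMDN) X(CSQN_tot) X(Km_CSQN) \
  X(tni_koff_gain) \
  /* SR Ca fluxes */ \
  X(v_up) X(Km_up) X(plb_km_red) X(nu1_rel) X(nu2_leak) X(tau_tr) X(tau_xfer) \
  /* RyR Markov */ \
  X(ryr_kap) X(ryr_kam) X(ryr_kbp) X(ryr_kbm) X(ryr_kcp) X(ryr_kcm) \
  X(ryr_fwd_scale) X(ryr_bwd_scale) \
  X(pryr_decay) X(pryr_drive) X(ICaL_max_norm) \
  /* L-type Ca channel Markov */ \
  X(G_CaL) X(E_CaL) X(ltcc_frac_cav) X(G_CaLp_factor) \
  X(ltcc_a0) X(ltcc_b0) X(ltcc_Kpc_max) X(ltcc_Kpc_half) X(ltcc_gamma_hill) X(ltcc_Kpcb) X(ltcc_kvi) X(ltcc_kvr) \
  X(ltcc_kco) X(ltcc_koc) X(ltcc_kcop) X(ltcc_kocp) X(ltcc_dVact_p) \
  X(ltcc_koc_Vh) X(ltcc_koc_Vs) \
  /* fast Na channel Markov */ \
  X(G_Na) X(G_Nap_factor) \
  /* K currents */ \
  X(G_Ktof) X(gktof_p_factor) X(iktof_shift_act) X(iktof_shift_inact) \
  X(G_Kur) X(gkur_p_gain) X(G_Kss) X(G_Kr) X(ikr_kf) X(ikr_kb) \
  X(ik1_gmax) X(ik1_km_ko) \
  /* Cl current */ \
  X(G_ClCa) X(Km_Cl) X(E_Cl) \
  /* pumps & exchangers */ \
  X(I_NaK_max) X(Km_Nai) X(Km_Ko_nak) X(plm_km_red) \
  X(k_NaCa) X(Km_Na_ncx) X(Km_Ca_ncx) X(eta_ncx) X(ksat_ncx) \
  X(I_pCa_max) X(Km_pCa) \
  X(G_Cab) X(G_Nab) \
  /* stimulus */ \
  X(stim_amp) X(stim_dur)

// ---------------------------------------------------------------------------
// Signaling states (local concentrations, uM; fractions dimensionless)
// ---------------------------------------------------------------------------
#define BM_SIG_STATES(X) \
  X(cAMP_cav) X(cAMP_ecav) X(cAMP_cyt) \
  X(GsaGTP_cav) X(GsaGTP_ecav) X(GsaGTP_cyt) \
  X(GsaGDP_cav) X(GsaGDP_ecav) X(GsaGDP_cyt) \
  X(Gsbg_cav) X(Gsbg_ecav) X(Gsbg_cyt) \
  X(Rpka_cav) X(Rpka_ecav) X(Rpka_cyt) \
  X(Rgrk_cav) X(Rgrk_ecav) X(Rgrk_cyt) \
  X(fPDE3_cav) X(fPDE3_cyt) \
  X(fPDE4_cav) X(fPDE4_ecav) X(fPDE4_cyt) \
  X(A2_cav) X(A4_cav) X(C_cav) X(CPKI_cav) \
  X(A2_ecav) X(A4_ecav) X(C_ecav) X(CPKI_ecav) \
  X(A2_cyt) X(A4_cyt) X(C_cyt) X(CPKI_cyt) \
  X(I1p_tot_cyt) \
  X(fLTCC_cav) X(fLTCC_ecav) X(fRyR) X(fINa) \
  X(fPLB) X(fTnI) X(fPLM) X(fIKur) X(fIKtof)

// ---------------------------------------------------------------------------
// Electrophysiological states (appended after signaling states in full mode)
// ---------------------------------------------------------------------------
#define BM_CELL_STATES(X) \
  X(V) \
  X(Cai) X(Cass) X(CaJSR) X(CaNSR) X(Nai) X(Ki) \
  X(LTRPNCa) X(HTRPNCa) X(PRyR) \
  X(ryr_C1) X(ryr_C2) X(ryr_O1) X(ryr_O2) \
  X(ryr_C1p) X(ryr_C2p) X(ryr_O1p) X(ryr_O2p) \
  X(lcav_C1) X(lcav_C2) X(lcav_C3) X(lcav_C4) X(lcav_CP) X(lcav_O) \
  X(lcav_I1) X(lcav_I2) X(lcav_I3) \
  X(lcav_C1p) X(lcav_C2p) X(lcav_C3p) X(lcav_C4p) X(lcav_CPp) X(lcav_Op) \
  X(lcav_I1p) X(lcav_I2p) X(lcav_I3p) \
  X(lecav_C1) X(lecav_C2) X(lecav_C3) X(lecav_C4) X(lecav_CP) X(lecav_O) \
  X(lecav_I1) X(lecav_I2) X(lecav_I3) \
  X(lecav_C1p) X(lecav_C2p) X(lecav_C3p) X(lecav_C4p) X(lecav_CPp) X(lecav_Op) \
  X(lecav_I1p) X(lecav_I2p) X(lecav_I3p) \
  X(na_C3) X(na_C2) X(na_C1) X(na_O) X(na_IF) X(na_I1) X(na_I2) \
  X(na_IC2) X(na_IC3) \
  X(na_C3p) X(na_C2p) X(na_C1p) X(na_Op) X(na_IFp) X(na_I1p) X(na_I2p) \
  X(na_IC2p) X(na_IC3p) \
  X(ato_f) X(ito_f) X(atop_f) X(itop_f) \
  X(aur) X(iur) X(aKss) \
  X(kr_C0) X(kr_C1) X(kr_C2) X(kr_O) X(kr_I)

// Derived/recorded quantities (currents pA/pF, fluxes uM/ms cytosol-normalized)
#define BM_CURRENTS(X) \
  X(ICaL) X(ICaL_cav) X(ICaL_ecav) X(IpCa) X(INaCa) X(ICab) \
  X(INa) X(INab) X(INaK) X(IKtof) X(IK1) X(IKur) X(IKss) X(IKr) X(IClCa) \
  X(Istim) X(Jrel) X(Jup) X(Jleak) X(Jtr) X(Jxfer)

#endif
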