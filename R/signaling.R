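#' Ligand-receptor-G-protein steady-state complexes
#'
#' Solves the algebraic receptor module: conservation of non-phosphorylated
#' beta1-adrenergic receptor (R_tot = R + LR + LRG + RG) and of stimulatory
#' G protein (Gs_tot = Gs + LRG + RG), with each complex given by the
#' steady-state approximation `[AB] = [A][B]/K`. Substitution reduces the
#' system to a quadratic in free receptor, solved in closed form (the
#' physical root is the unique non-negative one).
#'
#' @param L Ligand (isoproterenol) concentration, uM.
#' @param R_tot_np Non-phosphorylated receptor total, uM.
#' @param Gs_tot Available G-protein holoenzyme, uM.
#' @param K_L,K_H,K_C Dissociation constants (uM) for L+R, LR+G and R+G.
#' @return Named vector with `R`, `Gs` (free species) and the complexes
#'   `LR`, `LRG`, `RG`.
#' @export
solve_receptor_equilibrium <- function(L, R_tot_np, Gs_tot,
                                       K_L, K_H, K_C) {
  if (any(c(L, R_tot_np, Gs_tot) < 0)) {
    stop("receptor equilibrium inputs must be non-negative")
  }
  if (any(c(K_L, K_H, K_C) <= 0)) {
    stop("dissociation constants must be positive")
  }
  bm_receptor_equilibrium_cpp(L, R_tot_np, Gs_tot, K_L, K_H, K_C)
}

# compartments are indexed cav=1, ecav=2, cyt=3 throughout
.bm_comp <- function(compartment) {
  i <- match(compartment, c("cav", "ecav", "cyt"))
  if (is.na(i)) stop("unknown compartment: ", compartment)
  i
}

#' Adenylyl cyclase cAMP synthesis rate
#'
#' AC5/6 (caveolae) and AC4/7 (extracaveolae/cytosol) synthesis as a
#' saturating Hill function of active Gs-alpha with a multiplicative
#' Gs-betagamma boost; a basal turnover fraction keeps the unstimulated
#' rate positive. Normalized activity approaches 1 for large Gs-alpha.
#'
#' @param Gsa,Gsbg Active G-protein subunit concentrations, uM.
#' @param compartment `"cav"`, `"ecav"` or `"cyt"`.
#' @param model A `bm_model`.
#' @param normalized If `TRUE`, return activity normalized to its
#'   saturating value instead of uM/ms.
#' @return Synthesis rate (uM/ms) or normalized activity.
#' @export
ac_synthesis_rate <- function(Gsa, Gsbg, compartment, model,
                              normalized = FALSE) {
  if (any(Gsa < 0) || any(Gsbg < 0)) stop("G-protein inputs must be >= 0")
  i <- .bm_comp(compartment)
  p <- model$params
  conc <- c(p[["AC56_conc_cav"]], p[["AC47_conc_ecav"]], p[["AC47_conc_cyt"]])[i]
  kcat <- c(p[["kcat_AC56"]], p[["kcat_AC47"]], p[["kcat_AC47"]])[i]
  b <- c(p[["ACb_frac_cav"]], p[["ACb_frac_ecav"]], p[["ACb_frac_cyt"]])[i]
  K <- c(p[["K_AC56_gsa"]], p[["K_AC47_gsa"]], p[["K_AC47_gsa"]])[i]
  sbg <- c(p[["s_AC56_gbg"]], p[["s_AC47_gbg"]], p[["s_AC47_gbg"]])[i]
  Kbg <- c(p[["K_AC56_gbg"]], p[["K_AC47_gbg"]], p[["K_AC47_gbg"]])[i]
  h <- p[["h_AC_gsa"]]
  act <- ifelse(Gsa > 0, Gsa^h / (Gsa^h + K^h), 0)
  boost <- 1 + ifelse(Gsbg > 0, sbg * Gsbg / (Gsbg + Kbg), 0)
  rate <- conc * kcat * (b + (1 - b) * act) * boost
  if (normalized) (b + (1 - b) * act) else rate
}

#' Phosphodiesterase cAMP degradation rate
#'
#' Sum of per-isoform Michaelis-Menten terms (PDE2, PDE3, PDE4) with
#' phosphorylation of PDE3/PDE4 scaling their catalytic activity up and
#' inhibitor multipliers scaling it down. The extracaveolae compartment
#' contains no PDE3.
#'
#' @param cAMP cAMP concentration, uM.
#' @param compartment `"cav"`, `"ecav"` or `"cyt"`.
#' @param model `bm_model`.
#' @param f_pde3,f_pde4 Phosphorylated fractions in `[0,1]`.
#' @param pde3_mult,pde4_mult,ibmx_mult Inhibition multipliers in `[0,1]`.
#' @return Degradation rate, uM/ms (local concentration units).
#' @export
pde_degradation_rate <- function(cAMP, compartment, model,
                                 f_pde3 = 0, f_pde4 = 0,
                                 pde3_mult = 1, pde4_mult = 1,
                                 ibmx_mult = 1) {
  if (any(cAMP < 0)) stop("cAMP must be >= 0")
  stopifnot(all(c(pde3_mult, pde4_mult, ibmx_mult) >= 0),
            all(c(pde3_mult, pde4_mult, ibmx_mult) <= 1),
            all(f_pde3 >= 0 & f_pde3 <= 1), all(f_pde4 >= 0 & f_pde4 <= 1))
  i <- .bm_comp(compartment)
  p <- model$params
  c2 <- c(p[["PDE2_cav"]], p[["PDE2_ecav"]], p[["PDE2_cyt"]])[i]
  c3 <- c(p[["PDE3_cav"]], 0, p[["PDE3_cyt"]])[i]
  c4 <- c(p[["PDE4_cav"]], p[["PDE4_ecav"]], p[["PDE4_cyt"]])[i]
  r2 <- p[["kcat_PDE2"]] * c2 * cAMP / (cAMP + p[["Km_PDE2"]])
  r3 <- p[["kcat_PDE3"]] * c3 * (1 + p[["delta_PDE3_phos"]] * f_pde3) *
    cAMP / (cAMP + p[["Km_PDE3"]]) * pde3_mult
  r4 <- p[["kcat_PDE4"]] * c4 * (1 + p[["delta_PDE4_phos"]] * f_pde4) *
    cAMP / (cAMP + p[["Km_PDE4"]]) * pde4_mult
  ibmx_mult * (r2 + r3 + r4)
}

#' PKA activation chain right-hand side
#'
#' Time derivatives of the PKA species in one compartment at a clamped
#' cAMP concentration. The holoenzyme binds four cAMP in two cooperative
#' steps of two molecules (identical site affinities), then releases its
#' two catalytic subunits; free catalytic subunit is buffered by PKI.
#'
#' @param cAMP Clamped cAMP, uM.
#' @param species Named vector with `A2`, `A4`, `C`, `CPKI` (uM).
#' @param compartment `"cav"`, `"ecav"` or `"cyt"`.
#' @param model `bm_model`.
#' @param pka_scale Scale on total PKA (0 emulates H-89).
#' @return Named vector of derivatives (uM/ms).
#' @export
pka_balance_rhs <- function(cAMP, species, compartment, model,
                            pka_scale = 1) {
  stopifnot(all(species >= 0), cAMP >= 0)
  i <- .bm_comp(compartment)
  p <- model$params
  Ktot <- c(p[["PKA_tot_cav"]], p[["PKA_tot_ecav"]], p[["PKA_tot_cyt"]])[i] *
    pka_scale
  Kd <- c(p[["K_PKAII"]], p[["K_PKAII"]], p[["K_PKAI"]])[i]
  PKItot <- c(p[["PKI_tot_cav"]], p[["PKI_tot_ecav"]], p[["PKI_tot_cyt"]])[i]
  A2 <- species[["A2"]]; A4 <- species[["A4"]]
  C <- species[["C"]]; CPKI <- species[["CPKI"]]
  A0 <- max(Ktot - 0.5 * (C + CPKI) - A2 - A4, 0)
  D <- 0.5 * (C + CPKI)
  kon <- p[["k_pka_camp_on"]]
  r1 <- kon * (A0 * cAMP^2 - Kd^2 * A2)
  r2 <- kon * (A2 * cAMP^2 - Kd^2 * A4)
  kdb <- p[["k_pka_diss"]] / p[["K_pka_diss"]]
  r3 <- p[["k_pka_diss"]] * A4 - kdb * D * C^2
  r4 <- p[["k_pki_on"]] * C * max(PKItot - CPKI, 0) - p[["k_pki_off"]] * CPKI
  c(A2 = r1 - r2, A4 = r2 - r3, C = 2 * r3 - r4, CPKI = r4)
}

#' Equilibrium PKA activation at clamped cAMP
#'
#' Algebraic equilibrium of the binding chain (used for activation curves
#' and as the deterministic complement of [pka_balance_rhs()]). Solves for
#' free catalytic subunit by one-dimensional root bracketing on the
#' catalytic-mass conservation residual.
#'
#' @inheritParams pka_balance_rhs
#' @return Named vector: equilibrium `A0`, `A2`, `A4`, `C`, `CPKI` and the
#'   activation ratio `C_over_total`.
#' @export
pka_equilibrium <- function(cAMP, compartment, model, pka_scale = 1) {
  i <- .bm_comp(compartment)
  p <- model$params
  Ktot <- c(p[["PKA_tot_cav"]], p[["PKA_tot_ecav"]], p[["PKA_tot_cyt"]])[i] *
    pka_scale
  Kd <- c(p[["K_PKAII"]], p[["K_PKAII"]], p[["K_PKAI"]])[i]
  PKItot <- c(p[["PKI_tot_cav"]], p[["PKI_tot_ecav"]], p[["PKI_tot_cyt"]])[i]
  KD <- p[["K_pka_diss"]]
  KPKI <- p[["k_pki_off"]] / p[["k_pki_on"]]
  if (Ktot <= 0) {
    return(c(A0 = 0, A2 = 0, A4 = 0, C = 0, CPKI = 0, C_over_total = 0))
  }
  if (cAMP <= 0) {
    # no cAMP: the binding chain empties and all catalytic subunit rebinds
    return(c(A0 = Ktot, A2 = 0, A4 = 0, C = 0, CPKI = 0, C_over_total = 0))
  }
  x <- (cAMP / Kd)^2
  resid <- function(C) {
    CPKI <- C * PKItot / (KPKI + C)
    D <- 0.5 * (C + CPKI)
    # A4 from dissociation equilibrium, then chain closure
    A4 <- D * C^2 / KD
    A2 <- if (x > 0) A4 / x else 0
    A0 <- if (x > 0) A2 / x else Ktot
    (A0 + A2 + A4 + D) - Ktot
  }
  lo <- 0; hi <- 2 * Ktot
  while (resid(hi) < 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) > 0) hi <- mid else lo <- mid
  }
  C <- 0.5 * (lo + hi)
  CPKI <- C * PKItot / (KPKI + C)
  D <- 0.5 * (C + CPKI)
  A4 <- D * C^2 / KD
  A2 <- if (x > 0) A4 / x else 0
  A0 <- if (x > 0 && A2 > 0) A2 / x else Ktot - A2 - A4 - D
  c(A0 = A0, A2 = A2, A4 = A4, C = C, CPKI = CPKI,
    C_over_total = (C + CPKI) / (2 * Ktot))
}

#' Inhibitor-1 / PP1 steady-state complex
#'
#' Closed-form (quadratic, physical branch) solution of the conservation
#' system for the high-affinity interaction of phosphorylated inhibitor-1
#' with protein phosphatase 1.
#'
#' @param I1p_total Total phosphorylated inhibitor-1, uM.
#' @param PP1_total Total PP1, uM.
#' @param K_Inhib1 Dissociation constant, uM.
#' @return Named vector: `PP1_free`, `complex`, `I1p_free`.
#' @export
inhibitor1_pp1_equilibrium <- function(I1p_total, PP1_total, K_Inhib1) {
  if (any(c(I1p_total, PP1_total) < 0) || K_Inhib1 <= 0) {
    stop("inputs must be non-negative and K > 0")
  }
  b <- I1p_total + PP1_total + K_Inhib1
  disc <- b^2 - 4 * I1p_total * PP1_total
  stopifnot(disc >= 0)
  cmplx <- 0.5 * (b - sqrt(disc))
  cmplx <- min(max(cmplx, 0), I1p_total, PP1_total)
  c(PP1_free = PP1_total - cmplx, complex = cmplx,
    I1p_free = I1p_total - cmplx)
}

#' cAMP balance right-hand side
#'
#' Per-compartment d[cAMP]/dt from synthesis, degradation, PKA buffering
#' and inter-compartment diffusion, evaluated on a full signaling state.
#' The diffusive fluxes are pairwise antisymmetric in amount units, so with
#' synthesis, degradation and PKA binding switched off the volume-weighted
#' total is conserved.
#'
#' @param state Signaling state vector (45 states).
#' @param model `bm_model`.
#' @param ctx Drug [context()].
#' @return Named vector `c(cav = , ecav = , cyt = )`, uM/ms.
#' @export
camp_rhs <- function(state, model, ctx = context()) {
  dy <- bm_rhs_cpp(unname(state), unname(model$params), 0, unclass(ctx), 0L)
  setNames(dy[1:3], c("cav", "ecav", "cyt"))
}

#' Receptor desensitization right-hand side
#'
#' Time derivatives of PKA- and GRK2-phosphorylated receptor pools in one
#' compartment. PKA phosphorylates ligand-bound, G-protein-bound and free
#' receptors alike; GRK2 acts only on ligand-bound states, so its forward
#' term vanishes at zero ligand.
#'
#' @param L Ligand concentration, uM.
#' @param R_pka,R_grk Phosphorylated receptor pools, uM.
#' @param C Catalytic PKA subunit, uM.
#' @param PP Local phosphatase activity, uM.
#' @param compartment `"cav"`, `"ecav"` or `"cyt"`.
#' @param model `bm_model`.
#' @param Gs_avail Available G-protein holoenzyme, uM.
#' @return Named vector `c(dR_pka = , dR_grk = )`, uM/ms.
#' @export
receptor_desensitization_rhs <- function(L, R_pka, R_grk, C, PP,
                                         compartment, model,
                                         Gs_avail = NULL) {
  stopifnot(all(c(L, R_pka, R_grk, C, PP) >= 0))
  i <- .bm_comp(compartment)
  p <- model$params
  v <- c(p[["v_cav"]], p[["v_ecav"]], p[["v_cyt"]])[i]
  fr <- c(p[["Rb1_frac_cav"]], p[["Rb1_frac_ecav"]], p[["Rb1_frac_cyt"]])[i]
  Rt <- p[["Rb1_tot_cell"]] * fr / v
  if (is.null(Gs_avail)) {
    Gs_avail <- c(p[["Gs_tot_cav"]], p[["Gs_tot_ecav"]], p[["Gs_tot_cyt"]])[i]
  }
  Rtnp <- max(Rt - R_pka - R_grk, 0)
  eq <- solve_receptor_equilibrium(L, Rtnp, Gs_avail,
                                   p[["K_b1_L"]], p[["K_b1_H"]], p[["K_b1_C"]])
  c(dR_pka = p[["k_bar_pka"]] * C / (p[["Km_bar_pka"]] + C) * Rtnp -
      p[["k_bar_pka_dp"]] * PP * R_pka,
    dR_grk = p[["k_bar_grk"]] * (eq[["LR"]] + eq[["LRG"]]) -
      p[["k_bar_grk_dp"]] * PP * R_grk)
}

#' Whole-cell quantities from a signaling state
#'
#' Volume-weighted whole-cell cAMP and free catalytic PKA concentrations.
#'
#' @param state Signaling (or full) state vector.
#' @param model `bm_model`.
#' @return Named vector `c(cAMP = , C = )`, uM (normalized to V_cell).
#' @export
whole_cell_signaling <- function(state, model) {
  p <- model$params
  v <- c(p[["v_cav"]], p[["v_ecav"]], p[["v_cyt"]])
  camp <- sum(v * state[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")])
  Cc <- sum(v * state[c("C_cav", "C_ecav", "C_cyt")])
  c(cAMP = unname(camp), C = unname(Cc))
}

#' Receptor phosphorylation level of a signaling state
#'
#' Cell-volume-weighted fraction of beta1-adrenergic receptors in the PKA-
#' or GRK2-phosphorylated pools.
#'
#' @param state Signaling state vector.
#' @param model `bm_model`.
#' @return Named vector with `total`, `pka`, `grk` phosphorylated fractions.
#' @export
receptor_phosphorylation <- function(state, model) {
  p <- model$params
  v <- c(p[["v_cav"]], p[["v_ecav"]], p[["v_cyt"]])
  amt_pka <- sum(v * state[c("Rpka_cav", "Rpka_ecav", "Rpka_cyt")])
  amt_grk <- sum(v * state[c("Rgrk_cav", "Rgrk_ecav", "Rgrk_cyt")])
  tot <- p[["Rb1_tot_cell"]]
  c(total = (amt_pka + amt_grk) / tot, pka = amt_pka / tot,
    grk = amt_grk / tot)
}
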