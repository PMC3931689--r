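#' Membrane potential derivative
#'
#' Convention: `dV/dt = -(I_CaL + I_p(Ca) + I_NaCa + I_Cab + I_Na + I_Nab +
#' I_NaK + I_Kto,f + I_K1 + I_Kur + I_Kss + I_Kr + I_Cl,Ca - I_stim)` with
#' currents in pA/pF and specific capacitance 1 uF/cm^2, so a +80 pA/pF
#' stimulus alone depolarizes at +80 mV/ms.
#'
#' @param currents Named vector of membrane currents, pA/pF.
#' @param I_stim Stimulus current, pA/pF.
#' @return dV/dt, mV/ms.
#' @export
membrane_rhs <- function(currents, I_stim = 0) {
  nm <- c("ICaL", "IpCa", "INaCa", "ICab", "INa", "INab", "INaK",
          "IKtof", "IK1", "IKur", "IKss", "IKr", "IClCa")
  -(sum(currents[nm]) - I_stim)
}

#' Evaluate all membrane currents and Ca2+/Na+ fluxes at a state
#'
#' @param model `bm_model`.
#' @param state Full-cell state vector.
#' @param ctx Drug/protocol [context()].
#' @param t Absolute time (only affects the stimulus term), ms.
#' @return Named vector of currents (pA/pF) and fluxes (uM/ms).
#' @export
model_currents <- function(model, state, ctx = context(), t = 0) {
  bm_currents_cpp(unname(state), unname(model$params), t, unclass(ctx))
}

#' Na+/K+ pump current with phospholemman modulation
#'
#' Phosphorylated phospholemman lowers the pump's Na+ half-saturation
#' constant, increasing the current at fixed intracellular Na+.
#'
#' @param model `bm_model`.
#' @param V Membrane potential, mV.
#' @param Nai Intracellular Na+, uM.
#' @param f_PLM Phospholemman phosphorylated fraction in `[0,1]`.
#' @return Current, pA/pF.
#' @export
nak_current <- function(model, V, Nai, f_PLM = 0) {
  stopifnot(f_PLM >= 0, f_PLM <= 1)
  p <- model$params
  RTF <- p[["Rgas"]] * p[["TempK"]] / p[["Farad"]]
  sigma <- (exp(p[["Nao"]] / 67300) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                 0.0365 * sigma * exp(-V / RTF))
  KmNai <- p[["Km_Nai"]] * (1 - p[["plm_km_red"]] * f_PLM)
  unname(p[["I_NaK_max"]] * fNaK / (1 + (KmNai / Nai)^1.5) *
           p[["Ko"]] / (p[["Ko"]] + p[["Km_Ko_nak"]]))
}

#' SERCA uptake flux with phospholamban modulation
#'
#' Phosphorylated phospholamban releases its brake on SERCA by lowering the
#' pump's Ca2+ half-saturation constant.
#'
#' @param model `bm_model`.
#' @param Cai Cytosolic Ca2+, uM.
#' @param f_PLB Phospholamban phosphorylated fraction.
#' @return J_up, uM/ms.
#' @export
serca_flux <- function(model, Cai, f_PLB = 0) {
  stopifnot(f_PLB >= 0, f_PLB <= 1)
  p <- model$params
  Km <- p[["Km_up"]] * (1 - p[["plb_km_red"]] * f_PLB)
  unname(p[["v_up"]] * Cai^2 / (Cai^2 + Km^2))
}

#' Troponin Ca2+ unbinding rates with TnI phosphorylation
#'
#' Linear mixing: phosphorylation of troponin I raises the Ca2+ unbinding
#' rate by 50 % at full phosphorylation.
#'
#' @param model `bm_model`.
#' @param f_TnI Troponin-I phosphorylated fraction.
#' @return Named vector with low- and high-affinity site unbinding rates
#'   (1/ms).
#' @export
troponin_buffer_rates <- function(model, f_TnI = 0) {
  stopifnot(f_TnI >= 0, f_TnI <= 1)
  p <- model$params
  g <- 1 + p[["tni_koff_gain"]] * f_TnI
  c(k_ltrpn_off = unname(p[["k_ltrpn_m"]] * g),
    k_htrpn_off = unname(p[["k_htrpn_m"]] * g))
}

#' PKA-modulated K+ currents
#'
#' I_Kur grows with its phosphorylated fraction (conductance gain); peak
#' I_Kto,f falls roughly two-fold at full phosphorylation and its
#' phosphorylated gating carries depolarizing shifts of activation and
#' steady-state inactivation.
#'
#' @param model `bm_model`.
#' @param V Membrane potential, mV.
#' @param gates Named vector with `ato_f`, `ito_f`, `atop_f`, `itop_f`,
#'   `aur`, `iur`.
#' @param f_IKur,f_IKtof Phosphorylated fractions.
#' @param EK K+ reversal potential, mV.
#' @return Named vector `c(IKur = , IKtof = )`, pA/pF.
#' @export
modulated_k_currents <- function(model, V, gates, f_IKur = 0, f_IKtof = 0,
                                 EK = -85) {
  stopifnot(f_IKur >= 0, f_IKur <= 1, f_IKtof >= 0, f_IKtof <= 1)
  p <- model$params
  ikur <- p[["G_Kur"]] * (1 + p[["gkur_p_gain"]] * f_IKur) *
    gates[["aur"]] * gates[["iur"]] * (V - EK)
  iktof <- p[["G_Ktof"]] * (V - EK) *
    ((1 - f_IKtof) * gates[["ato_f"]]^3 * gates[["ito_f"]] +
       f_IKtof * p[["gktof_p_factor"]] * gates[["atop_f"]]^3 *
         gates[["itop_f"]])
  c(IKur = unname(ikur), IKtof = unname(iktof))
}

#' Per-cycle integral flux ledger
#'
#' Integrates the recorded Ca2+ and Na+ pathway fluxes over one stimulus
#' period of a paced trajectory (trapezoid rule on the recording grid) and
#' reports them in uM normalized to the cytosolic volume, the bookkeeping
#' used for cardiac-cycle flux budgets.
#'
#' @param model `bm_model`.
#' @param traj Paced `bm_trajectory` with currents recorded.
#' @param window Numeric `c(t_start, t_end)` in ms spanning exactly one
#'   stimulus period at periodic steady state.
#' @return Named list with the Ca2+ entries (`J_CaL`, `J_up_minus_leak`,
#'   `J_rel`, `J_NaCa_out`, `J_pCa`, `J_Cab_in`) and Na+ entries
#'   (`J_Nav`, `J_Nab`, `J_NaCa_Na_in`, `J_NaK_out`), plus a periodicity
#'   drift metric.
#' @export
accumulate_fluxes <- function(model, traj, window) {
  stopifnot(!is.null(traj$currents))
  p <- model$params
  sel <- traj$time >= window[1] & traj$time <= window[2]
  if (sum(sel) < 10) stop("window contains too few samples")
  tt <- traj$time[sel]
  cur <- traj$currents[sel, , drop = FALSE]
  conv2 <- p[["Acap"]] * p[["Cm"]] / (2 * p[["V_myo"]] * p[["Farad"]])
  conv1 <- p[["Acap"]] * p[["Cm"]] / (p[["V_myo"]] * p[["Farad"]])
  trap <- function(v) sum(diff(tt) * (head(v, -1) + tail(v, -1)) / 2)
  drift <- abs(traj$states[max(which(sel)), "Cai"] -
                 traj$states[min(which(sel)), "Cai"]) /
    max(traj$states[sel, "Cai"])
  list(
    J_CaL = -trap(cur[, "ICaL"]) * conv2,
    J_up_minus_leak = trap(cur[, "Jup"] - cur[, "Jleak"]),
    J_rel = trap(cur[, "Jrel"]) * p[["V_jsr"]] / p[["V_myo"]],
    J_NaCa_out = -2 * trap(cur[, "INaCa"]) * conv2,
    J_pCa = trap(cur[, "IpCa"]) * conv2,
    J_Cab_in = -trap(cur[, "ICab"]) * conv2,
    J_Nav = -trap(cur[, "INa"]) * conv1,
    J_Nab = -trap(cur[, "INab"]) * conv1,
    J_NaCa_Na_in = -3 * trap(cur[, "INaCa"]) * conv1,
    J_NaK_out = 3 * trap(cur[, "INaK"]) * conv1,
    periodicity_drift = drift)
}
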