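#' Markov generator matrices at clamped conditions
#'
#' Return the infinitesimal generator (columns = source states) of one
#' channel Markov model at clamped voltage/Ca2+ and fixed phosphorylation /
#' dephosphorylation rates. Columns sum to zero (probability conservation);
#' the stationary distribution is the null space.
#'
#' @param model `bm_model`.
#' @param V Membrane potential, mV.
#' @param Ca Local Ca2+ (subspace for the L-type channel and RyR), uM.
#' @param kphos,kdeph Phosphorylation/dephosphorylation rates, 1/ms.
#' @return Square generator matrix with state names.
#' @export
ltcc_generator <- function(model, V, Ca, kphos = 0, kdeph = 0) {
  G <- bm_ltcc_generator_cpp(V, Ca, kphos, kdeph, unname(model$params))
  nm <- sub("^lcav_", "", grep("^lcav_", bm_cell_state_names_cpp(),
                               value = TRUE))
  dimnames(G) <- list(nm, nm)
  G
}

#' @rdname ltcc_generator
#' @export
na_generator <- function(model, V, kphos = 0, kdeph = 0) {
  G <- bm_na_generator_cpp(V, kphos, kdeph)
  nm <- sub("^na_", "", grep("^na_", bm_cell_state_names_cpp(), value = TRUE))
  dimnames(G) <- list(nm, nm)
  G
}

#' @rdname ltcc_generator
#' @export
ryr_generator <- function(model, Ca, kphos = 0, kdeph = 0) {
  G <- bm_ryr_generator_cpp(Ca, kphos, kdeph, unname(model$params))
  nm <- sub("^ryr_", "", grep("^ryr_", bm_cell_state_names_cpp(),
                              value = TRUE))
  dimnames(G) <- list(nm, nm)
  G
}

#' L-type Ca2+ channel occupancy derivatives
#'
#' Right-hand side of one L-type population (18 states: 9 per
#' phosphorylation sub-diagram) at clamped conditions. Derivatives sum to
#' zero exactly (generator property).
#'
#' @param occupancy Occupancy vector of length 18.
#' @inheritParams ltcc_generator
#' @return Derivative vector.
#' @export
ltcc_rhs <- function(model, occupancy, V, Ca, kphos = 0, kdeph = 0) {
  stopifnot(length(occupancy) == 18)
  as.vector(ltcc_generator(model, V, Ca, kphos, kdeph) %*% occupancy)
}

#' @rdname ltcc_rhs
#' @export
nav_rhs <- function(model, occupancy, V, kphos = 0, kdeph = 0) {
  stopifnot(length(occupancy) == 18)
  as.vector(na_generator(model, V, kphos, kdeph) %*% occupancy)
}

#' L-type Ca2+ current of one population
#'
#' `I = G_CaL * w_pop * (O + 2.09 O_p) * (V - E_CaL)` where `w_pop` is the
#' population weight (20 % caveolae, 80 % extracaveolae) and the
#' phosphorylated open state carries the larger unitary conductance.
#'
#' @param model `bm_model`.
#' @param occupancy 18-state occupancy vector (O and O_p are used).
#' @param V Membrane potential, mV.
#' @param population `"cav"` or `"ecav"`.
#' @return Current, pA/pF.
#' @export
ltcc_current <- function(model, occupancy, V, population = c("ecav", "cav")) {
  population <- match.arg(population)
  p <- model$params
  w <- if (population == "cav") p[["ltcc_frac_cav"]] else
    1 - p[["ltcc_frac_cav"]]
  O <- occupancy[6]; Op <- occupancy[15]
  unname(p[["G_CaL"]] * w * (O + p[["G_CaLp_factor"]] * Op) *
           (V - p[["E_CaL"]]))
}

#' RyR open probability versus cytosolic Ca2+
#'
#' Stationary open probability of the ryanodine-receptor Markov chain at
#' clamped Ca2+, for the intact model or with PKA absent (emulating boiled
#' kinase). Computed by integrating the clamped chain to its stationary
#' distribution; phosphorylated and non-phosphorylated curves nearly
#' coincide because forward and backward Ca2+-dependent rates are sped up
#' almost proportionally.
#'
#' @param model `bm_model`.
#' @param Ca_grid Cytosolic Ca2+ grid, uM (0.01 to 10 typical).
#' @param pka_on If `FALSE`, the chain is confined to the
#'   non-phosphorylated sub-diagram.
#' @param kphos,kdeph Phosphorylation-cycle rates while clamped, 1/ms.
#' @return Data frame with `Ca` and `P_open`.
#' @export
ryr_open_probability <- function(model, Ca_grid, pka_on = TRUE,
                                 kphos = 1e-4, kdeph = 1e-4) {
  stopifnot(all(Ca_grid >= 0))
  if (!pka_on) kphos <- 0
  po <- vapply(Ca_grid, function(ca) {
    y <- c(1, rep(0, 7))
    G <- bm_ryr_generator_cpp(ca, kphos, kdeph, unname(model$params))
    # propagate exp(G t) by scaling-and-squaring of a short-step Taylor
    # propagator until the distribution is stationary
    h <- 0.05 / max(abs(diag(G)), 1e-12)
    M <- diag(8); Tk <- diag(8)
    for (k in 1:8) {
      Tk <- (Tk %*% G) * (h / k)
      M <- M + Tk
    }
    for (k in 1:70) {
      M <- M %*% M
      # exact propagators are column-stochastic; renormalize so repeated
      # squaring cannot drift or overflow
      M <- sweep(M, 2, colSums(M), "/")
    }
    y <- as.vector(M %*% y)
    y <- pmax(y, 0); y <- y / sum(y)
    sum(y[c(3, 4, 7, 8)])  # O1, O2, O1p, O2p
  }, numeric(1))
  data.frame(Ca = Ca_grid, P_open = po)
}

#' Scalar phosphorylation-fraction kinetics
#'
#' Shared two-state balance for the scalar PKA targets (PLB, TnI, PLM,
#' IKur, IKto,f and the lumped channel fractions):
#' `df/dt = kp * C * (1 - f) - kd * PP * f`, with steady state
#' `kp C / (kp C + kd PP)`.
#'
#' @param fraction Phosphorylated fraction in `[0,1]`.
#' @param C Catalytic PKA subunit, uM.
#' @param PP Phosphatase activity, uM.
#' @param kp,kd Forward/backward rate coefficients (1/uM/ms).
#' @return Derivative (1/ms).
#' @export
phosphofraction_rhs <- function(fraction, C, PP, kp, kd) {
  stopifnot(fraction >= 0, fraction <= 1, C >= 0, PP >= 0)
  kp * C * (1 - fraction) - kd * PP * fraction
}

#' @rdname phosphofraction_rhs
#' @export
phosphofraction_ss <- function(C, PP, kp, kd) {
  fwd <- kp * C; bwd <- kd * PP
  ifelse(fwd + bwd > 0, fwd / (fwd + bwd), 0)
}

#' Phosphorylated-branch occupancy of a Markov state vector
#'
#' @param state Full-cell state vector.
#' @param channel `"ltcc_cav"`, `"ltcc_ecav"`, `"na"` or `"ryr"`.
#' @return Fraction of total occupancy in the phosphorylated sub-diagram.
#' @export
phospho_fraction_markov <- function(state,
                                    channel = c("ltcc_cav", "ltcc_ecav",
                                                "na", "ryr")) {
  channel <- match.arg(channel)
  pre <- switch(channel, ltcc_cav = "lcav", ltcc_ecav = "lecav",
                na = "na", ryr = "ryr")
  nm <- grep(paste0("^", pre, "_"), names(state), value = TRUE)
  ph <- nm[grepl("p$", nm)]
  sum(state[ph]) / sum(state[nm])
}
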