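test_that("receptor equilibrium handles the no-ligand and empty-receptor limits", {
  m <- bm_test_model()
  p <- m$params
  KL <- p[["K_b1_L"]]; KH <- p[["K_b1_H"]]; KC <- p[["K_b1_C"]]

  # L = 0: no ligand-bound complexes; R and RG partition by the R-Gs
  # equilibrium alone (two-species closed form)
  eq <- solve_receptor_equilibrium(0, 0.1, 5, KL, KH, KC)
  expect_equal(unname(eq[["LR"]]), 0)
  expect_equal(unname(eq[["LRG"]]), 0)
  expect_equal(unname(eq[["R"]] + eq[["RG"]]), 0.1, tolerance = 1e-12)
  expect_equal(unname(eq[["RG"]]), unname(eq[["R"]] * eq[["Gs"]] / KC),
               tolerance = 1e-10)

  # no receptor: everything zero, Gs free
  eq0 <- solve_receptor_equilibrium(1, 0, 5, KL, KH, KC)
  expect_equal(unname(eq0[["LR"]] + eq0[["LRG"]] + eq0[["RG"]]), 0)
  expect_equal(unname(eq0[["Gs"]]), 5)

  expect_error(solve_receptor_equilibrium(-1, 1, 1, KL, KH, KC),
               "non-negative")
  expect_error(solve_receptor_equilibrium(1, 1, 1, 0, KH, KC), "positive")
})

test_that("receptor equilibrium matches the brute-force oracle and conserves mass", {
  m <- bm_test_model()
  p <- m$params
  KL <- p[["K_b1_L"]]; KH <- p[["K_b1_H"]]; KC <- p[["K_b1_C"]]
  # ledger-like parameter set at L = 1 uM against the independent
  # root-bracketing oracle
  eq <- solve_receptor_equilibrium(1, 0.1274, 15.8, KL, KH, KC)
  or <- receptor_equilibrium_bruteforce(1, 0.1274, 15.8, KL, KH, KC)
  expect_equal(unname(eq), unname(or), tolerance = 1e-8)

  # property: both conservation laws to <= 1e-10 over random inputs
  set.seed(42)
  for (k in 1:40) {
    L <- runif(1, 0, 10) * sample(c(0, 1), 1, prob = c(0.2, 0.8))
    Rt <- runif(1, 1e-4, 0.5)
    Gt <- runif(1, 0.1, 20)
    eq <- solve_receptor_equilibrium(L, Rt, Gt, KL, KH, KC)
    expect_lt(abs(eq[["R"]] + eq[["LR"]] + eq[["LRG"]] + eq[["RG"]] - Rt) /
                Rt, 1e-10)
    expect_lt(abs(eq[["Gs"]] + eq[["LRG"]] + eq[["RG"]] - Gt) / Gt, 1e-10)
    expect_true(all(eq >= 0))
  }
})

test_that("adenylyl cyclase activity is basal at rest, monotone and saturating", {
  m <- bm_test_model()
  for (cc in c("cav", "ecav", "cyt")) {
    r0 <- ac_synthesis_rate(0, 0, cc, m)
    expect_gt(r0, 0)
    grid <- c(0, 10^seq(-4, 2, length.out = 30))
    r <- ac_synthesis_rate(grid, 0, cc, m)
    expect_true(all(diff(r) >= 0))
    expect_equal(ac_synthesis_rate(1e7, 0, cc, m, normalized = TRUE), 1,
                 tolerance = 1e-5)
  }
  # midpoint against a direct evaluation of the ledger formula
  p <- m$params
  K <- p[["K_AC56_gsa"]]; b <- p[["ACb_frac_cav"]]; h <- p[["h_AC_gsa"]]
  expect_equal(ac_synthesis_rate(K, 0, "cav", m, normalized = TRUE),
               unname(b + (1 - b) * 0.5), tolerance = 1e-12)
  expect_error(ac_synthesis_rate(1, 0, "mitochondria", m), "unknown")
})

test_that("PDE degradation follows the per-isoform Michaelis sum and inhibitors", {
  m <- bm_test_model()
  p <- m$params
  expect_equal(pde_degradation_rate(0, "cav", m), 0)
  # independent per-isoform evaluation at 1 uM cAMP in the caveolae
  f3 <- 0.2; f4 <- 0.3
  oracle <- p[["kcat_PDE2"]] * p[["PDE2_cav"]] * 1 / (1 + p[["Km_PDE2"]]) +
    p[["kcat_PDE3"]] * p[["PDE3_cav"]] * (1 + p[["delta_PDE3_phos"]] * f3) *
      1 / (1 + p[["Km_PDE3"]]) +
    p[["kcat_PDE4"]] * p[["PDE4_cav"]] * (1 + p[["delta_PDE4_phos"]] * f4) *
      1 / (1 + p[["Km_PDE4"]])
  expect_equal(pde_degradation_rate(1, "cav", m, f3, f4), unname(oracle),
               tolerance = 1e-12)
  # 90 % selective PDE4 inhibition scales only the PDE4 term
  full <- pde_degradation_rate(1, "cyt", m, f3, f4)
  inh <- pde_degradation_rate(1, "cyt", m, f3, f4, pde4_mult = 0.1)
  term4 <- p[["kcat_PDE4"]] * p[["PDE4_cyt"]] *
    (1 + p[["delta_PDE4_phos"]] * f4) * 1 / (1 + p[["Km_PDE4"]])
  expect_equal(full - inh, unname(0.9 * term4), tolerance = 1e-12)
  # extracaveolae holds no PDE3
  expect_equal(pde_degradation_rate(1, "ecav", m, f3, 0, pde3_mult = 0.1),
               pde_degradation_rate(1, "ecav", m, f3, 0), tolerance = 1e-15)
  # phosphorylation increases activity
  expect_gt(pde_degradation_rate(1, "cav", m, 0.9, 0.9),
            pde_degradation_rate(1, "cav", m, 0, 0))
})

test_that("PKA chain equilibrium matches a brute-force ODE relaxation", {
  m <- bm_test_model()
  # oracle: integrate the balance ODEs at clamped cAMP to steady state
  relax <- function(camp, comp) {
    y <- c(A2 = 0, A4 = 0, C = 0, CPKI = 0)
    for (k in 1:400000) {
      dy <- pka_balance_rhs(camp, y, comp, m)
      y <- pmax(y + 0.5 * dy, 0)
    }
    y
  }
  for (camp in c(0.5, 2.5, 8)) {
    y <- relax(camp, "ecav")
    eq <- pka_equilibrium(camp, "ecav", m)
    expect_equal(unname(y[["C"]]), unname(eq[["C"]]), tolerance = 1e-3)
    # equilibrium is a fixed point of the balance RHS
    dy <- pka_balance_rhs(camp, eq[c("A2", "A4", "C", "CPKI")], "ecav", m)
    expect_lt(max(abs(dy)), 1e-8)
  }
  # activation rises sigmoidally and saturates; PKAI vs PKAII ordering at
  # low cAMP follows the half-activation constants (2.9 vs 2.5 uM)
  grid <- 10^seq(-2, 1.5, length.out = 25)
  actII <- vapply(grid, function(cc)
    pka_equilibrium(cc, "ecav", m)[["C_over_total"]], numeric(1))
  actI <- vapply(grid, function(cc)
    pka_equilibrium(cc, "cyt", m)[["C_over_total"]], numeric(1))
  expect_true(all(diff(actII) > -1e-12))
  expect_true(all(diff(actI) > -1e-12))
  # normalized activation is sigmoidal; the effective half-activation of
  # the released-subunit fraction sits below the per-site binding constant
  # because dissociation is cooperative in cAMP
  nrm <- actII / max(actII)
  half <- grid[min(which(nrm >= 0.5))]
  expect_gt(half, 0.05); expect_lt(half, 8)
  expect_gt(max(actII), 0.3)
  # with PKA removed (H-89 emulation) there is no catalytic subunit
  expect_equal(pka_equilibrium(5, "cav", m, pka_scale = 0)[["C"]], 0)
})

test_that("inhibitor-1/PP1 closed form agrees with bisection to 1e-12", {
  eq <- inhibitor1_pp1_equilibrium(0, 0.15, 1e-3)
  expect_equal(unname(eq[["PP1_free"]]), 0.15)
  expect_equal(unname(eq[["complex"]]), 0)
  # K -> infinity: no binding
  eqK <- inhibitor1_pp1_equilibrium(0.1, 0.1, 1e9)
  expect_lt(eqK[["complex"]], 1e-9)
  # bisection oracle on the conservation residual
  K <- 0.001; I1 <- 0.1; PP <- 0.1
  resid <- function(cm) (I1 - cm) * (PP - cm) / K - cm
  lo <- 0; hi <- min(I1, PP)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  eq2 <- inhibitor1_pp1_equilibrium(I1, PP, K)
  expect_equal(unname(eq2[["complex"]]), (lo + hi) / 2, tolerance = 1e-12)
  expect_error(inhibitor1_pp1_equilibrium(-1, 1, 1), "non-negative")
})

test_that("cAMP diffusion conserves amount and relaxes at the eigen rate", {
  # reaction-free configuration: AC, PDE and PKA binding all disabled
  led <- load_ledger(overrides = c(kcat_AC56 = 0, kcat_AC47 = 0,
                                   k_pka_camp_on = 0))
  m0 <- build_model(led)
  ctx0 <- context(ibmx_mult = 0)
  y <- initial_state(m0, "signaling")

  # equal concentrations: diffusive equilibrium, all three derivatives zero
  y_eq <- y
  y_eq[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")] <- 0.7
  expect_equal(unname(camp_rhs(y_eq, m0, ctx0)), c(0, 0, 0),
               tolerance = 1e-15)

  # step in the caveolae: trajectory matches the closed-form linear system
  y1 <- y
  y1[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")] <- c(5, 0, 0)
  tr <- simulate_segment(m0, y1, 20000, ctx0, record_dt = 500, rtol = 1e-10)
  camp <- tr$states[, 1:3]
  p <- m0$params
  v <- c(p[["v_cav"]], p[["v_ecav"]], p[["v_cyt"]])
  # amount conservation along the trajectory
  amount <- camp %*% v
  expect_lt(max(abs(amount - amount[1])) / amount[1], 1e-8)
  # closed-form solution via the eigen-decomposition of the exchange matrix
  g <- c(p[["J_camp_cav_ecav"]], p[["J_camp_cav_cyt"]],
         p[["J_camp_ecav_cyt"]])
  A <- matrix(0, 3, 3)
  A[1, ] <- c(-(g[1] + g[2]), g[1], g[2]) / v[1]
  A[2, ] <- c(g[1], -(g[1] + g[3]), g[3]) / v[2]
  A[3, ] <- c(g[2], g[3], -(g[2] + g[3])) / v[3]
  ev <- eigen(A)
  c0 <- solve(ev$vectors, c(5, 0, 0))
  for (i in c(5, 20, 41)) {
    pred <- Re(ev$vectors %*% (c0 * exp(ev$values * tr$time[i])))
    expect_equal(unname(camp[i, ]), as.vector(pred), tolerance = 1e-6)
  }
})

test_that("GRK2 phosphorylation is strictly ligand-gated", {
  m <- bm_test_model()
  d0 <- receptor_desensitization_rhs(0, 0.001, 0.002, 0.05, 0.3, "ecav", m)
  # no ligand: only dephosphorylation of the GRK pool remains
  expect_lt(d0[["dR_grk"]], 0)
  d1 <- receptor_desensitization_rhs(1, 0.001, 0.002, 0.05, 0.3, "ecav", m)
  expect_gt(d1[["dR_grk"]], d0[["dR_grk"]])
  # steady state of the PKA pool equals the closed-form two-state balance
  p <- m$params
  Csat <- 0.05 / (p[["Km_bar_pka"]] + 0.05)
  kf <- p[["k_bar_pka"]] * Csat
  kb <- p[["k_bar_pka_dp"]] * 0.3
  Rt <- p[["Rb1_tot_cell"]] * p[["Rb1_frac_ecav"]] / p[["v_ecav"]]
  f_ss <- kf / (kf + kb)
  d_at_ss <- receptor_desensitization_rhs(0, f_ss * Rt, 0, 0.05, 0.3,
                                          "ecav", m)
  expect_equal(unname(d_at_ss[["dR_pka"]]), 0, tolerance = 1e-12)
})

test_that("receptor and G-protein mass is conserved along trajectories", {
  m <- bm_test_model()
  y <- bm_basal_sig()
  tr <- simulate_segment(m, y, 60000, context(iso = 1), record_dt = 5000)
  p <- m$params
  # total Gs-derived mass per compartment: holoenzyme is implicit, so check
  # Gsbg = GsaGTP + GsaGDP (activation produces both in lockstep)
  for (cc in c("cav", "ecav", "cyt")) {
    bg <- tr$states[, paste0("Gsbg_", cc)]
    aa <- tr$states[, paste0("GsaGTP_", cc)] +
      tr$states[, paste0("GsaGDP_", cc)]
    expect_lt(max(abs(bg - aa)) / max(bg), 1e-6)
    # phosphorylated pools never exceed the compartment allocation
    fr <- p[[paste0("Rb1_frac_", cc)]]
    Rt <- p[["Rb1_tot_cell"]] * fr / p[[paste0("v_", cc)]]
    expect_true(all(tr$states[, paste0("Rpka_", cc)] +
                      tr$states[, paste0("Rgrk_", cc)] <= Rt + 1e-12))
  }
  expect_true(all(tr$states >= -1e-10))
})
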