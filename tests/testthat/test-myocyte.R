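test_that("membrane equation slope follows the stated sign convention", {
  cur <- setNames(rep(0, 13),
                  c("ICaL", "IpCa", "INaCa", "ICab", "INa", "INab", "INaK",
                    "IKtof", "IK1", "IKur", "IKss", "IKr", "IClCa"))
  expect_equal(membrane_rhs(cur, I_stim = 80), 80)
  cur["IK1"] <- 2
  expect_equal(membrane_rhs(cur), -2)
})

test_that("Na+/K+ pump rises with Nai and with phospholemman phosphorylation", {
  m <- bm_test_model()
  expect_lt(nak_current(m, -80, 1, 0), 1e-4)      # no internal Na+
  ngrid <- seq(2000, 30000, length.out = 10)
  i0 <- vapply(ngrid, function(n) nak_current(m, -80, n, 0), numeric(1))
  expect_true(all(diff(i0) > 0))
  expect_gt(nak_current(m, -80, 10000, 1), nak_current(m, -80, 10000, 0))
  # reduced half-saturation matches a direct formula evaluation
  p <- m$params
  Km_red <- p[["Km_Nai"]] * (1 - p[["plm_km_red"]])
  ratio <- (1 + (Km_red / 10000)^1.5)^-1 / (1 + (p[["Km_Nai"]] / 10000)^1.5)^-1
  expect_equal(nak_current(m, -80, 10000, 1) / nak_current(m, -80, 10000, 0),
               unname(ratio), tolerance = 1e-12)
})

test_that("SERCA flux responds to phospholamban phosphorylation", {
  m <- bm_test_model()
  expect_equal(serca_flux(m, 0, 0), 0)
  expect_gt(serca_flux(m, 0.2, 1), serca_flux(m, 0.2, 0))
  p <- m$params
  for (f in c(0, 1)) {
    Km <- p[["Km_up"]] * (1 - p[["plb_km_red"]] * f)
    expect_equal(serca_flux(m, 0.3, f),
                 unname(p[["v_up"]] * 0.09 / (0.09 + Km^2)),
                 tolerance = 1e-12)
  }
})

test_that("troponin I phosphorylation scales Ca2+ unbinding linearly", {
  m <- bm_test_model()
  r0 <- troponin_buffer_rates(m, 0)
  r1 <- troponin_buffer_rates(m, 1)
  rh <- troponin_buffer_rates(m, 0.5)
  expect_equal(unname(r1 / r0), c(1.5, 1.5), tolerance = 1e-12)
  expect_equal(unname(rh), unname((r0 + r1) / 2), tolerance = 1e-12)
})

test_that("PKA-modulated K+ currents move in opposite directions", {
  m <- bm_test_model()
  gates <- c(ato_f = 0.6, ito_f = 0.8, atop_f = 0.6, itop_f = 0.8,
             aur = 0.5, iur = 0.9)
  i0 <- modulated_k_currents(m, 0, gates, 0, 0)
  i1 <- modulated_k_currents(m, 0, gates, 1, 1)
  expect_gt(i1[["IKur"]], i0[["IKur"]])      # IKur is potentiated
  expect_lt(i1[["IKtof"]], i0[["IKtof"]])    # IKto,f is suppressed
  # at f = 0 the control formulas apply exactly
  p <- m$params
  expect_equal(i0[["IKur"]],
               unname(p[["G_Kur"]] * 0.5 * 0.9 * (0 - (-85))),
               tolerance = 1e-12)
  # roughly two-fold reduction of the fully phosphorylated IKto,f
  expect_equal(i1[["IKtof"]] / i0[["IKtof"]],
               unname(p[["gktof_p_factor"]]), tolerance = 1e-12)
})

test_that("phosphorylated IKto,f gating carries depolarizing shifts", {
  m <- bm_test_model()
  y <- bm_basal_cell()
  # steady-state activation of the two gate sets at a test potential:
  # relax the gating ODEs at clamped V and compare
  relax_gates <- function(V) {
    cx <- context(clamp = TRUE, clamp_V = V)
    y2 <- y; y2["V"] <- V
    tr <- simulate_segment(bm_test_model(), y2, 3000, cx, record_dt = 3000)
    tr$states[nrow(tr$states), c("ato_f", "atop_f")]
  }
  g <- relax_gates(-20)
  expect_lt(g[["atop_f"]], g[["ato_f"]])  # activation shifted depolarized
})

test_that("flux accumulation returns zero integrals for a silent membrane", {
  m <- bm_test_model()
  fake <- list(time = seq(0, 1000, by = 1),
               states = matrix(0.1, nrow = 1001, ncol = 2,
                               dimnames = list(NULL, c("Cai", "V"))),
               currents = matrix(0, nrow = 1001, ncol = 21,
                                 dimnames = list(NULL, bm_current_names())))
  class(fake) <- "bm_trajectory"
  fl <- accumulate_fluxes(m, fake, c(0, 1000))
  expect_equal(fl$J_CaL, 0)
  expect_equal(fl$J_NaK_out, 0)
  expect_equal(fl$J_rel, 0)
})

test_that("the resting myocyte is electrically quiescent and stable", {
  m <- bm_test_model()
  y <- bm_basal_cell()
  tr <- simulate_segment(m, y, 10000, context(), record_dt = 1000)
  V <- tr$states[, "V"]
  expect_lt(abs(V[length(V)] - V[6]), 0.05)        # < 0.05 mV drift over 5 s
  expect_true(all(V > -95 & V < -70))
  dy <- model_deriv(m, tr$states[nrow(tr$states), ])
  expect_lt(abs(dy[["V"]]), 1e-3)
})
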