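test_that("Markov generators conserve probability (columns sum to zero)", {
  m <- bm_test_model()
  set.seed(7)
  for (k in 1:8) {
    V <- runif(1, -100, 50); Ca <- runif(1, 0.05, 30)
    kp <- runif(1, 0, 1e-3); kd <- runif(1, 0, 1e-3)
    for (G in list(ltcc_generator(m, V, Ca, kp, kd),
                   na_generator(m, V, kp, kd),
                   ryr_generator(m, Ca, kp, kd))) {
      expect_lt(max(abs(colSums(G))), 1e-12)
      expect_true(all(G[row(G) != col(G)] >= 0))
    }
  }
})

test_that("occupancy derivatives sum to zero exactly", {
  m <- bm_test_model()
  set.seed(11)
  occ <- runif(18); occ <- occ / sum(occ)
  expect_lt(abs(sum(ltcc_rhs(m, occ, 0, 5, 1e-4, 1e-4))), 1e-14)
  expect_lt(abs(sum(nav_rhs(m, occ, -30, 1e-4, 1e-4))), 1e-14)
})

test_that("clamped chains converge to the generator null space", {
  m <- bm_test_model()
  cases <- list(
    list(gen = function() ltcc_generator(m, -40, 0.5, 2e-4, 1e-4), n = 18),
    list(gen = function() ltcc_generator(m, 0, 5, 1e-4, 2e-4), n = 18),
    list(gen = function() na_generator(m, -80, 1e-4, 1e-4), n = 18),
    list(gen = function() ryr_generator(m, 0.3, 1e-4, 1e-4), n = 8))
  for (cs in cases) {
    G <- cs$gen()
    pi_ns <- stationary_nullspace(G)           # linear-algebra oracle
    y0 <- c(1, rep(0, cs$n - 1))
    pi_sim <- propagate_generator(G, y0, squarings = 70)
    expect_equal(pi_sim, unname(pi_ns), tolerance = 1e-6)
    expect_equal(sum(pi_ns), 1, tolerance = 1e-9)
  }
})

test_that("basal L-type phosphorylation is 10.3 % of the cellular population", {
  # each population carries its own basal fraction; the 20/80
  # population-weighted total is the published 10.3 %
  m <- bm_test_model()
  y <- bm_basal_sig()
  p <- m$params
  f <- c(cav = NA_real_, ecav = NA_real_)
  for (pop in c("cav", "ecav")) {
    C <- y[[paste0("C_", pop)]]
    PP <- if (pop == "cav") p[["PP1_cav"]] + p[["PP2A_cav"]] else
      p[["PP1_ecav"]]
    kp <- p[[paste0("kp_ltcc_", pop)]] * C
    kd <- p[[paste0("kd_ltcc_", pop)]] * PP
    G <- ltcc_generator(m, -80, 0.1, kp, kd)
    pi <- stationary_nullspace(G)
    f[pop] <- sum(pi[10:18])
    # stationary phospho fraction matches the two-state balance
    expect_equal(sum(pi[10:18]), kp * 1 / (kp + kd) / 1, tolerance = 0.01)
  }
  w <- p[["ltcc_frac_cav"]]
  expect_equal(unname(w * f[["cav"]] + (1 - w) * f[["ecav"]]), 0.103,
               tolerance = 0.05)
})

test_that("RyR open probability rises with Ca2+ and is PKA-insensitive", {
  m <- bm_test_model()
  grid <- 10^seq(-2, 1, length.out = 12)
  on <- ryr_open_probability(m, grid, pka_on = TRUE)
  off <- ryr_open_probability(m, grid, pka_on = FALSE)
  expect_lt(on$P_open[1], 1e-4)             # Ca -> 0 closes the channel
  sub <- grid <= 1
  expect_true(all(diff(on$P_open[sub]) > 0))
  # phosphorylation shifts sensitivity only marginally
  expect_lt(max(abs(on$P_open - off$P_open)), 0.06)
  # stationary-distribution oracle at one Ca point
  G <- ryr_generator(m, grid[6], 1e-4, 1e-4)
  pi <- stationary_nullspace(G)
  expect_equal(on$P_open[6], sum(pi[c(3, 4, 7, 8)]), tolerance = 1e-4)
})

test_that("scalar phosphorylation kinetics obey the two-state balance", {
  expect_equal(phosphofraction_ss(0, 0.3, 1e-4, 1e-4), 0)
  expect_equal(phosphofraction_ss(0.5, 0.25, 2e-4, 4e-4),
               2e-4 * 0.5 / (2e-4 * 0.5 + 4e-4 * 0.25), tolerance = 1e-14)
  # derivative drives the fraction toward the steady state
  f_ss <- phosphofraction_ss(0.1, 0.2, 1e-4, 3e-4)
  expect_gt(phosphofraction_rhs(f_ss - 0.1, 0.1, 0.2, 1e-4, 3e-4), 0)
  expect_lt(phosphofraction_rhs(f_ss + 0.1, 0.1, 0.2, 1e-4, 3e-4), 0)
  expect_equal(phosphofraction_rhs(f_ss, 0.1, 0.2, 1e-4, 3e-4), 0,
               tolerance = 1e-18)
})

test_that("L-type current vanishes in closed states and splits 20/80", {
  m <- bm_test_model()
  occ <- rep(0, 18); occ[1] <- 0.9; occ[10] <- 0.1   # all closed
  expect_equal(ltcc_current(m, occ, 0, "cav"), 0)
  occ2 <- rep(0, 18); occ2[6] <- 1                    # fully open, np
  icav <- ltcc_current(m, occ2, 0, "cav")
  iecav <- ltcc_current(m, occ2, 0, "ecav")
  expect_equal(icav / iecav, 0.2 / 0.8, tolerance = 1e-12)
  # phosphorylated open state carries the larger conductance
  occ3 <- rep(0, 18); occ3[15] <- 1
  expect_equal(ltcc_current(m, occ3, 0, "ecav") / iecav,
               unname(m$params[["G_CaLp_factor"]]), tolerance = 1e-12)
})

test_that("toy fixtures carry valid closed-form references", {
  fx <- make_toy_fixture("markov3state")
  expect_lt(max(abs(colSums(fx$generator))), 1e-14)
  expect_equal(as.vector(fx$generator %*% fx$stationary), rep(0, 3),
               tolerance = 1e-14)
  fb <- make_toy_fixture("biexp_trace", tau = c(4, 18))
  expect_equal(fb$tau, c(4, 18))
  f2 <- make_toy_fixture("twocomp_camp")
  expect_equal(sum(f2$A[, 1] * f2$v), 0, tolerance = 1e-18)
})
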