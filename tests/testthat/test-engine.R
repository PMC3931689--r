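test_that("zero-duration protocols return the initial state only", {
  m <- bm_test_model()
  y <- bm_basal_sig()
  tr <- simulate_segment(m, y, 0, context())
  expect_equal(nrow(tr$states), 1)
  expect_equal(unname(tr$states[1, ]), unname(y))
})

test_that("simulations are deterministic and continuous across events", {
  m <- bm_test_model()
  y <- bm_basal_sig()
  segs <- list(list(t_len = 5000, ctx = context()),
               list(t_len = 5000, ctx = context(iso = 0.1)))
  t1 <- simulate_segments(m, y, segs, record_dt = 500)
  t2 <- simulate_segments(m, y, segs, record_dt = 500)
  expect_identical(t1$states, t2$states)   # bit-identical reruns
  # state is continuous at the drug-application event
  i_ev <- which(t1$time == t1$events[1])
  expect_lt(max(abs(t1$states[i_ev, ] - t1$states[i_ev - 1, ])) /
              max(abs(t1$states[i_ev, ])), 0.05)
})

test_that("steady-state search converges and is idempotent", {
  m <- bm_test_model()
  y <- bm_basal_sig()
  # perturb away from the fixed point, then recover it
  y2 <- y
  y2[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")] <-
    y2[c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")] * 1.8
  ss <- find_steady_state(m, y2, window = 10000)
  expect_equal(unname(ss$state[1:3]), unname(y[1:3]), tolerance = 0.01)
  # an already-converged state converges immediately
  ss2 <- find_steady_state(m, ss$state, window = 10000)
  expect_equal(ss2$windows, 1)
  expect_error(find_steady_state(m, y, context(pacing = TRUE)),
               "unstimulated")
})

test_that("voltage clamp holds the commanded potential exactly", {
  m <- bm_test_model()
  y <- bm_basal_cell()
  steps <- data.frame(V = c(-80, 0, -80), dur = c(100, 50, 100))
  tr <- run_voltage_clamp(m, y, steps, record_dt = 1)
  expect_setequal(unique(tr$states[, "V"]), c(-80, 0))
  expect_error(run_voltage_clamp(m, y, data.frame(V = 0, dur = 0)),
               "overlapping")
})

test_that("adaptive and fixed-step engines agree on the biochemical subsystem", {
  # engine cross-validation on the (non-stiff) signaling network; the
  # paced full-cell comparison against the reference step policy lives in
  # the acceptance suite
  m <- bm_test_model()
  y <- bm_basal_sig()
  cx <- context(iso = 1)
  tr_a <- simulate_segment(m, y, 20000, cx, record_dt = 1000, rtol = 1e-9)
  tr_f <- simulate_segment(m, y, 20000, cx, record_dt = 1000,
                           engine = "rk4", dt_fixed = 1)
  rel <- abs(tr_a$states - tr_f$states) /
    (1e-9 + pmax(abs(tr_a$states), abs(tr_f$states)))
  expect_lt(max(rel), 1e-5)
})

test_that("halving tolerances leaves the AP metrics unchanged", {
  m <- bm_test_model()
  y <- bm_basal_cell()
  cx <- context(pacing = TRUE, stim_period = 1000)
  a1 <- simulate_segment(m, y, 100, cx, record_dt = 0.1, rtol = 1e-7)
  a2 <- simulate_segment(m, y, 100, cx, record_dt = 0.1, rtol = 5e-8)
  apd1 <- measure_apd(a1$time, a1$states[, "V"], 90)
  apd2 <- measure_apd(a2$time, a2$states[, "V"], 90)
  expect_lt(abs(apd1 - apd2) / apd1, 1e-3)
})

test_that("trajectories reject NaN and export tidy records", {
  m <- bm_test_model()
  y <- bm_basal_sig()
  tr <- simulate_segment(m, y, 1000, context(), record_dt = 500)
  df <- trajectory_tidy(tr, vars = c("cAMP_cav", "C_cyt"))
  expect_named(df, c("time", "variable", "value"))
  expect_equal(nrow(df), 2 * length(tr$time))
  tmp <- tempfile(fileext = ".csv")
  trajectory_write_csv(tr, tmp, vars = "cAMP_cav")
  expect_true(file.exists(tmp))
  back <- read.csv(tmp)
  expect_equal(back$value[1], unname(y[["cAMP_cav"]]), tolerance = 1e-8)
})
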