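#' Action-potential duration at a repolarization level
#'
#' APD_x is measured from the time of maximal upstroke velocity to the
#' linearly interpolated crossing of `peak - x% * amplitude`, where
#' amplitude = peak - resting potential (potential just before the
#' upstroke).
#'
#' @param time,V Sampled AP trace (one full action potential), ms and mV.
#' @param level Repolarization level: 25, 50, 75 or 90.
#' @return Duration, ms.
#' @export
measure_apd <- function(time, V, level) {
  stopifnot(level %in% c(25, 50, 75, 90), length(time) == length(V))
  dv <- diff(V) / diff(time)
  iup <- which.max(dv)
  t_up <- time[iup]
  ipk <- which.max(V)
  if (ipk <= iup) stop("no action potential found in trace")
  rest <- V[max(1, iup - 1)]
  peak <- V[ipk]
  thr <- peak - level / 100 * (peak - rest)
  after <- which(time > time[ipk] & V <= thr)
  if (length(after) == 0) stop("no APD", level, " crossing within trace")
  i2 <- after[1]; i1 <- i2 - 1
  t_cross <- time[i1] + (thr - V[i1]) * (time[i2] - time[i1]) /
    (V[i2] - V[i1])
  t_cross - t_up
}

#' Action-potential metrics of the last beat in a paced trajectory
#'
#' @param traj Paced `bm_trajectory`.
#' @param period Stimulus period, ms.
#' @param beat Which beat (counted from the end; 1 = last).
#' @return List of class `bm_ap_metrics`: resting and peak potential,
#'   amplitude (mV) and APD25/50/75/90 (ms).
#' @export
ap_metrics <- function(traj, period, beat = 1) {
  t_end <- max(traj$time)
  n_beats <- floor(t_end / period + 1e-9)
  t0 <- (n_beats - beat) * period
  sel <- traj$time >= t0 & traj$time <= t0 + period
  tt <- traj$time[sel] - t0
  V <- traj$states[sel, "V"]
  out <- list(resting = V[1], peak = max(V), amplitude = max(V) - V[1])
  for (lv in c(25, 50, 75, 90)) {
    out[[paste0("APD", lv)]] <- measure_apd(tt, V, lv)
  }
  class(out) <- "bm_ap_metrics"
  out
}

#' Ca2+ transient metrics of the last beat
#'
#' @param traj Paced `bm_trajectory`.
#' @param period Stimulus period, ms.
#' @param beat Which beat from the end.
#' @return List: diastolic/systolic Ca2+ (uM), amplitude, mono-exponential
#'   decay time constant tau (ms) and SR load (total JSR+NSR Ca2+, uM,
#'   normalized to SR volume).
#' @export
ca_metrics <- function(traj, period, beat = 1) {
  t_end <- max(traj$time)
  n_beats <- floor(t_end / period + 1e-9)
  t0 <- (n_beats - beat) * period
  sel <- traj$time >= t0 & traj$time <= t0 + period
  tt <- traj$time[sel] - t0
  ca <- traj$states[sel, "Cai"]
  dia <- ca[1]; ipk <- which.max(ca); sys <- ca[ipk]
  # decay tau from the fall from peak to diastolic baseline
  dec <- seq(ipk, length(ca))
  z <- ca[dec] - min(ca[dec])
  pos <- z > max(z) * 0.02
  tau <- tryCatch({
    fit <- stats::lm(log(z[pos]) ~ tt[dec][pos])
    -1 / coef(fit)[2]
  }, error = function(e) NA_real_)
  sr <- traj$states[sel, "CaJSR"] * 1 + traj$states[sel, "CaNSR"]
  list(diastolic = dia, systolic = sys, amplitude = sys - dia,
       tau_decay = unname(tau),
       sr_load = unname(traj$states[max(which(sel)), "CaNSR"]))
}

#' Bi-exponential decay fit
#'
#' Fits `A1 exp(-t/tau1) + A2 exp(-t/tau2) (+ C)` to a decaying trace by
#' nonlinear least squares; time constants are sorted so `tau_fast <
#' tau_slow`. The trace must start at its extremum.
#'
#' @param time,y Decay trace (e.g. -I_CaL from its peak).
#' @param baseline Add a constant offset term.
#' @return List with `tau_fast`, `tau_slow`, `A_fast`, `A_slow`,
#'   `baseline`, `r_squared`.
#' @export
fit_biexponential <- function(time, y, baseline = TRUE) {
  t0 <- time - time[1]
  span <- max(t0)
  ymax <- y[1]; ymin <- min(y)
  start <- list(a1 = 0.6 * (ymax - ymin), t1 = span / 20,
                a2 = 0.4 * (ymax - ymin), t2 = span / 4)
  df <- data.frame(t = t0, y = y)
  fit <- tryCatch({
    if (baseline) {
      nls(y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2) + c0, data = df,
          start = c(start, list(c0 = ymin)),
          control = list(maxiter = 500, warnOnly = FALSE))
    } else {
      nls(y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2), data = df,
          start = start, control = list(maxiter = 500, warnOnly = FALSE))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    # nls is fragile on exact (noise-free) traces; fall back to direct
    # least squares on the same model
    sse <- function(par) {
      pr <- exp(par)
      mu <- pr[1] * exp(-t0 / pr[2]) + pr[3] * exp(-t0 / pr[4]) +
        if (baseline) pr[5] - abs(ymin) - 1 else 0
      sum((y - mu)^2)
    }
    p0 <- log(c(max(start$a1, 1e-8), start$t1, max(start$a2, 1e-8),
                start$t2,
                if (baseline) abs(ymin) + 1 + 0 else NULL))
    op <- optim(p0, sse, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    if (!is.finite(op$value)) {
      stop("bi-exponential fit did not converge; residual norm: ",
           signif(op$value, 4))
    }
    pr <- exp(op$par)
    cf <- list(a1 = pr[1], t1 = pr[2], a2 = pr[3], t2 = pr[4],
               c0 = if (baseline) pr[5] - abs(ymin) - 1 else 0)
    resid_v <- y - (cf$a1 * exp(-t0 / cf$t1) + cf$a2 * exp(-t0 / cf$t2) +
                      cf$c0)
  } else {
    cf <- as.list(coef(fit))
    if (!baseline) cf$c0 <- 0
    resid_v <- residuals(fit)
  }
  taus <- sort(c(cf[["t1"]], cf[["t2"]]))
  amps <- c(cf[["a1"]], cf[["a2"]])[order(c(cf[["t1"]], cf[["t2"]]))]
  ss_res <- sum(resid_v^2)
  ss_tot <- sum((y - mean(y))^2)
  list(tau_fast = taus[1], tau_slow = taus[2],
       A_fast = amps[1], A_slow = amps[2],
       baseline = cf[["c0"]],
       r_squared = 1 - ss_res / ss_tot)
}

#' I_CaL inactivation time constants under voltage clamp
#'
#' From a basal full-cell steady state: hold at `V_hold`, step to
#' `V_step`, record total I_CaL and fit the decay from the current peak
#' with two exponentials. SR Ca2+ release can be disabled to emulate
#' heavy-buffer conditions.
#'
#' @param model `bm_model`.
#' @param state Basal full-cell state.
#' @param ctx Drug [context()] (clamp/no-CICR fields overwritten).
#' @param V_hold,V_step Holding and test potentials, mV.
#' @param t_step Test-pulse length, ms.
#' @param no_cicr Disable SR release during the pulse.
#' @param ... Passed to the integrator.
#' @return List with the fit (see [fit_biexponential()]), `peak` current
#'   and the recorded trace.
#' @export
icail_decay_experiment <- function(model, state, ctx = context(),
                                   V_hold = -80, V_step = 0, t_step = 100,
                                   no_cicr = TRUE, ...) {
  cx <- ctx
  cx$no_cicr <- as.integer(no_cicr)
  steps <- data.frame(V = c(V_hold, V_step), dur = c(500, t_step))
  traj <- run_voltage_clamp(model, state, steps, cx, record_dt = 0.05, ...)
  sel <- traj$time >= 500
  tt <- traj$time[sel] - 500
  ical <- traj$currents[sel, "ICaL"]
  ipk <- which.min(ical)
  fit <- fit_biexponential(tt[ipk:length(tt)] - tt[ipk],
                           -ical[ipk:length(tt)])
  list(fit = fit, peak = ical[ipk], time = tt, ICaL = ical,
       ICaL_cav = traj$currents[sel, "ICaL_cav"],
       ICaL_ecav = traj$currents[sel, "ICaL_ecav"])
}

#' Dose-response runner
#'
#' Exposes the biochemical subsystem to each agonist concentration for
#' `exposure_s` seconds and evaluates a readout function on the final
#' state.
#'
#' @param model `bm_model`.
#' @param iso_grid Isoproterenol concentrations, uM.
#' @param exposure_s Exposure, s.
#' @param readout Function of (state, model) returning a single number or
#'   a named vector.
#' @param basal Basal signaling steady state (computed if `NULL`).
#' @param ... Passed to the integrator.
#' @return Data frame with `iso` and the readout column(s).
#' @export
run_dose_response <- function(model, iso_grid, exposure_s, readout,
                              basal = NULL, ...) {
  if (length(iso_grid) == 0) {
    return(data.frame(iso = numeric(0)))
  }
  if (is.null(basal)) {
    basal <- find_steady_state(model, initial_state(model), ...)$state
  }
  rows <- lapply(iso_grid, function(L) {
    traj <- simulate_segment(model, basal, exposure_s * 1000,
                             context(iso = L), record_dt = exposure_s * 1000,
                             ...)
    val <- readout(traj$states[nrow(traj$states), ], model)
    c(iso = L, val)
  })
  as.data.frame(do.call(rbind, rows))
}

#' cAMP transient under pulsed isoproterenol with PDE inhibition
#'
#' Reproduces the pulsed-agonist protocol: optional 90 % selective
#' inhibition of PDE3 or PDE4 from t = 0, equilibration to the inhibited
#' steady state, then a 30-s pulse of 0.1 uM isoproterenol at t = 200 s.
#' Both amplitude definitions are computed (absolute peak of whole-cell
#' cAMP, and peak minus the pre-pulse baseline).
#'
#' @param model `bm_model`.
#' @param basal Basal signaling steady state.
#' @param pde3_mult,pde4_mult Isoform multipliers (0.1 = 90 % inhibition).
#' @param iso_pulse Pulse concentration, uM.
#' @param t_pre,t_pulse,t_post Segment durations, s.
#' @param ... Passed to the integrator.
#' @return List: `amplitude_peak`, `amplitude_rise`, `baseline`,
#'   `prepulse_vs_basal` (ratio), and the whole-cell cAMP trace.
#' @export
camp_pulse_experiment <- function(model, basal, pde3_mult = 1,
                                  pde4_mult = 1, iso_pulse = 0.1,
                                  t_pre = 200, t_pulse = 30, t_post = 170,
                                  ...) {
  ctx0 <- context(pde3_mult = pde3_mult, pde4_mult = pde4_mult)
  ctx1 <- context(iso = iso_pulse, pde3_mult = pde3_mult,
                  pde4_mult = pde4_mult)
  traj <- simulate_segments(
    model, basal,
    list(list(t_len = t_pre * 1000, ctx = ctx0, record_dt = 500),
         list(t_len = t_pulse * 1000, ctx = ctx1, record_dt = 100),
         list(t_len = t_post * 1000, ctx = ctx0, record_dt = 500)), ...)
  p <- model$params
  v <- c(p[["v_cav"]], p[["v_ecav"]], p[["v_cyt"]])
  camp <- as.vector(traj$states[, c("cAMP_cav", "cAMP_ecav", "cAMP_cyt")] %*% v)
  pre <- camp[max(which(traj$time <= t_pre * 1000))]
  basal_wc <- camp[1]
  pk <- max(camp[traj$time >= t_pre * 1000])
  list(amplitude_peak = pk, amplitude_rise = pk - pre, baseline = pre,
       prepulse_vs_basal = pre / basal_wc,
       time = traj$time, camp = camp)
}

#' L-type population block experiment
#'
#' Compares paced runs with one L-type Ca2+ channel population blocked
#' against the unblocked run under the same drug context, reporting APD50
#' and Ca2+ transient amplitude changes.
#'
#' @param model `bm_model`.
#' @param state Paced-steady full-cell state.
#' @param population `"none"`, `"cav"` or `"ecav"`.
#' @param iso Isoproterenol, uM.
#' @param freq_hz Pacing frequency.
#' @param n_beats Beats to pace before measuring.
#' @param ... Passed to the integrator.
#' @return List with `ap` and `ca` metrics of the final beat.
#' @export
run_block_experiment <- function(model, state, population = "none",
                                 iso = 0, freq_hz = 1, n_beats = 3, ...) {
  ctx <- context(iso = iso,
                 block_cav = population == "cav",
                 block_ecav = population == "ecav")
  period <- 1000 / freq_hz
  traj <- pace_model(model, state, freq_hz, n_beats * period / 1000, ctx,
                     record_dt = 0.2, ...)
  list(ap = ap_metrics(traj, period),
       ca = ca_metrics(traj, period))
}

#' Percentage change helper used by all treated-vs-control comparisons
#' @param treated,control Metric values from matched protocols.
#' @return 100 * (treated - control) / control.
#' @export
pct_change <- function(treated, control) 100 * (treated - control) / control
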