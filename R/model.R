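#' Build a simulation-ready model object
#'
#' Combines a parameter ledger with default initial conditions into the
#' object used by the simulation engine. The model carries the full state
#' layout of the compiled core: 45 signaling states (three-compartment
#' biochemistry) followed, in `"cell"` mode, by 84 electrophysiological
#' states (membrane potential, ionic concentrations, SR Ca2+ pools, buffers
#' and the Markov occupancy vectors).
#'
#' @param ledger A `bm_ledger` from [load_ledger()]; defaults to the
#'   shipped ledger.
#' @return An object of class `bm_model`.
#' @export
build_model <- function(ledger = load_ledger()) {
  m <- list(ledger = ledger, params = ledger_params(ledger))
  class(m) <- "bm_model"
  m
}

#' @export
print.bm_model <- function(x, ...) {
  cat("<bm_model> compartmentalized beta1-adrenergic myocyte model\n",
      " ledger checksum: ", x$ledger$checksum, "\n",
      " signaling states: ", length(bm_sig_state_names_cpp()),
      "; cell states: ", length(bm_cell_state_names_cpp()), "\n", sep = "")
  invisible(x)
}

#' Drug/protocol context
#'
#' A context fixes the pharmacological condition and stimulation mode for
#' one integration segment. Drugs are instantaneous parameter multipliers:
#' `iso` is the isoproterenol concentration (uM); `pde3_mult`/`pde4_mult`
#' scale the catalytic rate of one PDE isoform (0.1 = 90 % selective
#' inhibition); `ibmx_mult` scales all isoforms; `pka_scale` scales total
#' PKA (0 emulates H-89); `pp_scale` scales PP1/PP2A activity (0.35
#' emulates Calyculin A).
#'
#' @param iso Isoproterenol concentration, uM.
#' @param pde3_mult,pde4_mult,ibmx_mult PDE activity multipliers in `[0,1]`.
#' @param pka_scale,pp_scale Kinase/phosphatase scaling factors.
#' @param block_cav,block_ecav Logical; block one L-type population.
#' @param no_cicr Logical; disable SR Ca2+ release (heavy-buffer emulation).
#' @param clamp Logical; hold membrane potential at `clamp_V`.
#' @param clamp_V Command potential, mV.
#' @param pacing Logical; apply the stimulus-current train.
#' @param stim_t0 Time of first stimulus, ms.
#' @param stim_period Stimulus period, ms.
#' @return A list of class `bm_context`.
#' @export
context <- function(iso = 0, pde3_mult = 1, pde4_mult = 1, ibmx_mult = 1,
                    pka_scale = 1, pp_scale = 1,
                    block_cav = FALSE, block_ecav = FALSE, no_cicr = FALSE,
                    clamp = FALSE, clamp_V = -80,
                    pacing = FALSE, stim_t0 = 0, stim_period = 1000) {
  stopifnot(iso >= 0, pde3_mult >= 0, pde4_mult >= 0, ibmx_mult >= 0,
            pka_scale >= 0, pp_scale >= 0)
  if (clamp && pacing) {
    stop("clamp and current-stimulus modes are mutually exclusive")
  }
  ctx <- list(iso = iso, pde3_mult = pde3_mult, pde4_mult = pde4_mult,
              ibmx_mult = ibmx_mult, pka_scale = pka_scale,
              pp_scale = pp_scale,
              block_cav = as.integer(block_cav),
              block_ecav = as.integer(block_ecav),
              no_cicr = as.integer(no_cicr),
              clamp = as.integer(clamp), clamp_V = clamp_V,
              pacing = as.integer(pacing), stim_t0 = stim_t0,
              stim_period = stim_period)
  class(ctx) <- c("bm_context", "list")
  ctx
}

#' Initial state vectors from the ledger
#'
#' @param model A `bm_model`.
#' @param mode `"signaling"` (biochemistry only) or `"cell"` (full model).
#' @return Named numeric state vector.
#' @export
initial_state <- function(model, mode = c("signaling", "cell")) {
  mode <- match.arg(mode)
  ini <- model$ledger$initial
  sig <- unlist(ini$signaling)
  snames <- bm_sig_state_names_cpp()
  y <- sig[snames]
  if (anyNA(y)) stop("ledger initial conditions incomplete (signaling)")
  if (mode == "cell") {
    cell <- unlist(ini$cell)
    cnames <- bm_cell_state_names_cpp()
    y2 <- cell[cnames]
    if (anyNA(y2)) stop("ledger initial conditions incomplete (cell)")
    y <- c(y, y2)
    names(y) <- c(snames, cnames)
  }
  y
}

# internal mode id for the compiled core
.bm_mode <- function(mode) match.arg(mode, c("signaling", "cell")) == "cell"

#' Integrate the model over one context segment
#'
#' The default engine is an adaptive embedded Runge-Kutta (Cash-Karp 4(5))
#' with mixed error control; a fixed-step classical RK4 is available for
#' cross-validation, including the reference step policy of the original
#' implementation (fine step `dt_fine` for `fine_window` ms after each
#' stimulus onset, `dt_mid` otherwise during pacing, `dt_fixed` when
#' unstimulated).
#'
#' @param model `bm_model`.
#' @param state Named state vector (length 45 or 129).
#' @param t_len Segment duration, ms.
#' @param ctx A [context()].
#' @param record_dt Output sampling interval, ms.
#' @param engine `"adaptive"` or `"rk4"`.
#' @param rtol Relative tolerance (adaptive engine).
#' @param dt_fixed Fixed step (rk4 engine), ms.
#' @param max_dt Step-size cap for the adaptive engine, ms.
#' @param record_currents Record membrane currents and Ca2+/Na+ fluxes.
#' @param t0 Absolute start time (affects the stimulus phase), ms.
#' @param dt_fine,dt_mid,fine_window Reference step-policy knobs (rk4).
#' @return A `bm_trajectory`: list with `time`, `states` (matrix), optional
#'   `currents`, the context, solver diagnostics and the ledger checksum.
#' @export
simulate_segment <- function(model, state, t_len, ctx = context(),
                             record_dt = 10, engine = "adaptive",
                             rtol = 1e-7, dt_fixed = 0.1, max_dt = 5000,
                             record_currents = FALSE, t0 = 0,
                             dt_fine = 0, dt_mid = 1e-4, fine_window = 10) {
  stopifnot(inherits(model, "bm_model"), t_len >= 0)
  mode <- if (length(state) == length(bm_sig_state_names_cpp())) 0L else 1L
  if (t_len == 0) {
    traj <- list(time = t0, states = matrix(state, nrow = 1,
                                            dimnames = list(NULL, names(state))),
                 n_steps = 0, n_renorm = 0)
  } else {
    traj <- bm_simulate_cpp(unname(state), unname(model$params), t0,
                            t0 + t_len, record_dt, unclass(ctx), engine,
                            rtol, dt_fixed, max_dt, mode, record_currents,
                            dt_fine, dt_mid, fine_window)
    colnames(traj$states) <- names(state)
    if (!is.null(traj$currents)) colnames(traj$currents) <- bm_current_names_cpp()
  }
  traj$ctx <- ctx
  traj$checksum <- model$ledger$checksum
  if (any(!is.finite(traj$states))) stop("non-finite state in trajectory")
  class(traj) <- "bm_trajectory"
  traj
}

#' Run a multi-segment protocol
#'
#' Segments are integrated in order; the integrator restarts at every event
#' boundary so discontinuous drug applications are never stepped across.
#' State is continuous across events.
#'
#' @param model `bm_model`.
#' @param state Initial state vector.
#' @param segments List of `list(t_len = , ctx = , record_dt = )` entries;
#'   `record_dt` optional.
#' @param ... Passed to [simulate_segment()].
#' @return A `bm_trajectory` spanning the concatenated segments, with
#'   `events` marking the segment boundaries.
#' @export
simulate_segments <- function(model, state, segments, ...) {
  t0 <- 0
  out_t <- list(); out_s <- list(); out_c <- list()
  ev <- numeric(0)
  steps <- 0; renorm <- 0
  have_cur <- FALSE
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    args <- list(model = model, state = state, t_len = seg$t_len,
                 ctx = if (is.null(seg$ctx)) context() else seg$ctx, t0 = t0)
    if (!is.null(seg$record_dt)) args$record_dt <- seg$record_dt
    traj <- do.call(simulate_segment, c(args, list(...)))
    n <- length(traj$time)
    keep <- if (k > 1) -1 else TRUE   # drop duplicated boundary sample
    out_t[[k]] <- traj$time[keep]
    out_s[[k]] <- traj$states[keep, , drop = FALSE]
    if (!is.null(traj$currents)) {
      out_c[[k]] <- traj$currents[keep, , drop = FALSE]
      have_cur <- TRUE
    }
    state <- traj$states[n, ]
    t0 <- traj$time[n]
    ev <- c(ev, t0)
    steps <- steps + traj$n_steps; renorm <- renorm + traj$n_renorm
  }
  traj <- list(time = do.call(c, out_t), states = do.call(rbind, out_s),
               events = ev[-length(ev)], n_steps = steps, n_renorm = renorm,
               checksum = model$ledger$checksum)
  if (have_cur) traj$currents <- do.call(rbind, out_c)
  class(traj) <- "bm_trajectory"
  traj
}

#' @export
print.bm_trajectory <- function(x, ...) {
  cat("<bm_trajectory> ", length(x$time), " samples, t = [",
      min(x$time), ", ", max(x$time), "] ms, ",
      ncol(x$states), " states, ", format(x$n_steps, big.mark = ","),
      " solver steps\n", sep = "")
  invisible(x)
}

#' Tidy data frame / CSV export of a trajectory
#'
#' @param traj `bm_trajectory`.
#' @param vars Optional character vector of state/current names to keep.
#' @return Long data frame with columns `time`, `variable`, `value`.
#' @export
trajectory_tidy <- function(traj, vars = NULL) {
  M <- traj$states
  if (!is.null(traj$currents)) M <- cbind(M, traj$currents)
  if (!is.null(vars)) M <- M[, vars, drop = FALSE]
  data.frame(
    time = rep(traj$time, times = ncol(M)),
    variable = rep(colnames(M), each = nrow(M)),
    value = as.vector(M),
    stringsAsFactors = FALSE)
}

#' @rdname trajectory_tidy
#' @param path Output CSV path.
#' @export
trajectory_write_csv <- function(traj, path, vars = NULL) {
  df <- trajectory_tidy(traj, vars)
  attr(df, "ledger_checksum") <- traj$checksum
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Steady-state initialization
#'
#' Integrates the unstimulated model in windows of `window` ms and declares
#' convergence when the maximum relative change of every state variable
#' across a window falls below `tol` (mirroring the reference convergence
#' rule of "no variable changes by more than 0.01 %").
#'
#' @param model `bm_model`.
#' @param state Starting state.
#' @param ctx Drug context (must be unstimulated: no pacing).
#' @param window Window length, ms.
#' @param tol Relative-change tolerance per window.
#' @param max_windows Cap on the number of windows.
#' @param ... Passed to [simulate_segment()].
#' @return List with `state`, `windows` used, and `max_rel_change`.
#' @export
find_steady_state <- function(model, state = initial_state(model),
                              ctx = context(), window = 10000, tol = 1e-4,
                              max_windows = 400, ...) {
  if (ctx$pacing == 1L) stop("steady-state search requires an unstimulated model")
  for (w in seq_len(max_windows)) {
    traj <- simulate_segment(model, state, window, ctx,
                             record_dt = window, ...)
    newstate <- traj$states[nrow(traj$states), ]
    scale <- pmax(abs(state), 1e-9)
    rel <- abs(newstate - state) / scale
    state <- newstate
    if (max(rel) <= tol) {
      return(list(state = state, windows = w, max_rel_change = max(rel)))
    }
  }
  worst <- names(state)[which.max(rel)]
  stop("steady state not reached after ", max_windows,
       " windows; worst variable: ", worst,
       " (rel change ", signif(max(rel), 3), ")")
}

#' Voltage-clamp protocol runner
#'
#' Holds the membrane at a sequence of command potentials; the membrane ODE
#' is bypassed while every other state evolves. Steps must be
#' non-overlapping and are integrated in order.
#'
#' @param model `bm_model`.
#' @param state Full-cell state vector.
#' @param steps Data frame with columns `V` (mV) and `dur` (ms).
#' @param ctx Base drug context (its clamp fields are overwritten).
#' @param record_dt Sampling interval, ms.
#' @param ... Passed to [simulate_segment()].
#' @return `bm_trajectory` with recorded currents.
#' @export
run_voltage_clamp <- function(model, state, steps, ctx = context(),
                              record_dt = 0.1, ...) {
  stopifnot(is.data.frame(steps), all(c("V", "dur") %in% names(steps)))
  if (any(steps$dur <= 0)) stop("overlapping or empty clamp steps")
  segs <- lapply(seq_len(nrow(steps)), function(i) {
    cx <- ctx
    cx$clamp <- 1L; cx$clamp_V <- steps$V[i]; cx$pacing <- 0L
    list(t_len = steps$dur[i], ctx = cx, record_dt = record_dt)
  })
  state["V"] <- steps$V[1]
  traj <- simulate_segments(model, state, segs, record_currents = TRUE, ...)
  # V is held piecewise; write the commanded value into the record
  idx <- findInterval(traj$time, c(0, cumsum(steps$dur)),
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > nrow(steps)] <- nrow(steps)
  traj$states[, "V"] <- steps$V[idx]
  traj
}

#' Paced run at a fixed frequency
#'
#' @param model `bm_model`.
#' @param state Full-cell state.
#' @param freq_hz Pacing frequency, Hz.
#' @param duration_s Duration, s.
#' @param ctx Drug context (pacing fields overwritten).
#' @param record_dt Sampling interval, ms.
#' @param ... Passed to [simulate_segment()].
#' @return `bm_trajectory` with currents recorded.
#' @export
pace_model <- function(model, state, freq_hz, duration_s, ctx = context(),
                       record_dt = 0.5, ...) {
  cx <- ctx
  cx$pacing <- 1L; cx$clamp <- 0L
  cx$stim_t0 <- 0; cx$stim_period <- 1000 / freq_hz
  simulate_segment(model, state, duration_s * 1000, cx,
                   record_dt = record_dt, record_currents = TRUE, ...)
}

#' Map scalar phosphorylation fractions into Markov occupancies
#'
#' After a biochemistry-only exposure, the scalar L-type/RyR/Na+
#' phosphorylation fractions can be injected into a full-cell state by
#' rescaling the non-phosphorylated and phosphorylated halves of each
#' occupancy vector to the target fraction (occupancy shape within each
#' sub-diagram is preserved).
#'
#' @param cell_state Full-cell state vector.
#' @param sig_state Signaling state vector holding the exposed fractions.
#' @return Updated full-cell state.
#' @export
inject_phospho_fractions <- function(cell_state, sig_state) {
  y <- cell_state
  y[names(sig_state)] <- sig_state
  blocks <- list(
    list(pre = "lcav", n = 9, frac = sig_state[["fLTCC_cav"]]),
    list(pre = "lecav", n = 9, frac = sig_state[["fLTCC_ecav"]]),
    list(pre = "na", n = 9, frac = sig_state[["fINa"]]),
    list(pre = "ryr", n = 4, frac = sig_state[["fRyR"]]))
  for (b in blocks) {
    nm <- grep(paste0("^", b$pre, "_"), names(y), value = TRUE)
    np <- nm[!grepl("p$", nm)]
    ph <- nm[grepl("p$", nm)]
    s_np <- sum(y[np]); s_p <- sum(y[ph])
    if (s_np > 0) y[np] <- y[np] / s_np * (1 - b$frac)
    if (s_p > 0) {
      y[ph] <- y[ph] / s_p * b$frac
    } else {
      # move occupancy shape from the np diagram
      y[ph] <- y[np] / max(sum(y[np]), 1e-12) * b$frac
    }
  }
  y
}
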