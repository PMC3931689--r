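#' Name registries of the compiled core
#'
#' The compiled right-hand sides define the canonical ordering of
#' parameters, state variables and recorded currents; these accessors
#' expose those registries to R. `bm_state_names("cell")` returns the
#' electrophysiological states that are appended to the signaling states
#' in full-cell mode.
#'
#' @return Character vector of names.
#' @export
bm_param_names <- function() bm_param_names_cpp()

#' @rdname bm_param_names
#' @param mode `"signaling"` or `"cell"`.
#' @export
bm_state_names <- function(mode = c("signaling", "cell")) {
  mode <- match.arg(mode)
  if (mode == "signaling") bm_sig_state_names_cpp() else
    bm_cell_state_names_cpp()
}

#' @rdname bm_param_names
#' @export
bm_current_names <- function() bm_current_names_cpp()

#' Evaluate the model right-hand side at a state
#'
#' Returns the instantaneous time derivatives of every state variable,
#' for conservation checks and fixed-point diagnostics.
#'
#' @param model `bm_model`.
#' @param state Named state vector (signaling-only or full-cell length).
#' @param ctx Drug/protocol [context()].
#' @param t Absolute time (affects only the stimulus term), ms.
#' @return Named vector of derivatives.
#' @export
model_deriv <- function(model, state, ctx = context(), t = 0) {
  mode <- if (length(state) == length(bm_sig_state_names_cpp())) 0L else 1L
  dy <- bm_rhs_cpp(unname(state), unname(model$params), t, unclass(ctx),
                   mode)
  names(dy) <- names(state)
  dy
}
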