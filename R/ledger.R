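#' Load the model parameter ledger
#'
#' The ledger is the single source of truth for every numeric constant used
#' by the model: rate constants, concentrations, compartment volumes,
#' conductances and initial conditions. Each entry records its value, units,
#' compartment and a provenance tag (`main-text`, `base-model`, or `refit`
#' for constants recalibrated against the published curves because the
#' original supplement is not machine-readable), plus a short citation
#' string. A SHA-like checksum of the parameter block is attached so that
#' simulation outputs can record exactly which ledger produced them.
#'
#' @param path Path to a ledger JSON file. Defaults to the copy shipped
#'   with the package.
#' @param overrides Optional named numeric vector of parameter overrides
#'   (for sensitivity runs); names must exist in the ledger.
#' @return An object of class `bm_ledger`: a list with elements `params`
#'   (data frame of entries), `initial` (named list of initial-state
#'   groups), and `checksum`.
#' @export
load_ledger <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ledger.json", package = "betamyo")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("ledger file not found: ", path)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- as.data.frame(raw$params, stringsAsFactors = FALSE)
  required <- c("name", "value", "units", "compartment", "source", "cite")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    stop("ledger is malformed; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- params$name[duplicated(params$name)]
  if (length(dup) > 0) {
    stop("duplicate ledger entries: ", paste(unique(dup), collapse = ", "))
  }
  expected <- bm_param_names_cpp()
  absent <- setdiff(expected, params$name)
  if (length(absent) > 0) {
    stop("ledger is missing required parameters: ",
         paste(absent, collapse = ", "))
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), params$name)
    if (length(unknown) > 0) {
      stop("unknown parameter overrides: ", paste(unknown, collapse = ", "))
    }
    idx <- match(names(overrides), params$name)
    params$value[idx] <- as.numeric(overrides)
    params$source[idx] <- "override"
  }
  led <- list(params = params, initial = raw$initial)
  led$checksum <- ledger_checksum(led)
  class(led) <- "bm_ledger"
  led
}

#' Write a ledger back to JSON
#'
#' Round-trips [load_ledger()]: saving and re-loading reproduces the same
#' entries and checksum.
#'
#' @param ledger A `bm_ledger` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "bm_ledger"))
  jsonlite::write_json(
    list(params = ledger$params, initial = ledger$initial),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname load_ledger
#' @export
ledger_checksum <- function(ledger) {
  txt <- paste(ledger$params$name,
               formatC(ledger$params$value, digits = 17, format = "g"),
               collapse = ";")
  # small rolling checksum (no digest package in the environment)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("bm%010d", h)
}

#' Parameter vector in the order expected by the compiled core
#' @param ledger A `bm_ledger`.
#' @return Named numeric vector.
#' @export
ledger_params <- function(ledger) {
  stopifnot(inherits(ledger, "bm_ledger"))
  nm <- bm_param_names_cpp()
  v <- ledger$params$value[match(nm, ledger$params$name)]
  names(v) <- nm
  v
}

#' @export
print.bm_ledger <- function(x, ...) {
  src <- table(x$params$source)
  cat("<bm_ledger> ", nrow(x$params), " parameters, checksum ", x$checksum,
      "\n  provenance: ",
      paste(sprintf("%s=%d", names(src), as.integer(src)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# internal: consistency checks on the ledger's main-text totals
ledger_cross_checks <- function(ledger) {
  p <- ledger_params(ledger)
  list(
    beta1_ar_total = unname(p["Rb1_tot_cell"]),
    ac_total = unname(p["AC_tot_cell"]),
    i1_total_cell = unname(p["I1_tot_cyt"] * p["v_cyt"]),
    ac_conc_consistent = abs(
      p["AC56_conc_cav"] * p["v_cav"] +
        p["AC47_conc_ecav"] * p["v_ecav"] +
        p["AC47_conc_cyt"] * p["v_cyt"] -
        p["AC_tot_cell"]) < 1e-10
  )
}
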