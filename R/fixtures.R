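#' Synthetic test fixtures with closed-form references
#'
#' Small systems used by the test suite: a 3-state Markov chain with an
#' analytic stationary distribution, a sampled bi-exponential decay trace
#' with known time constants, and a reduced two-compartment linear cAMP
#' exchange system with its eigen-solution.
#'
#' @param kind `"markov3state"`, `"biexp_trace"` or `"twocomp_camp"`.
#' @param ... Fixture-specific options: `rates` (markov3state),
#'   `tau` / `amps` / `dt` / `t_end` (biexp_trace), `g` / `v` (twocomp_camp).
#' @return A list holding the system and its reference solution.
#' @export
make_toy_fixture <- function(kind = c("markov3state", "biexp_trace",
                                      "twocomp_camp"), ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  switch(kind,
    markov3state = {
      r <- opts$rates
      if (is.null(r)) r <- c(k12 = 0.4, k21 = 0.1, k23 = 0.05, k32 = 0.2)
      G <- matrix(0, 3, 3)
      G[1, 1] <- -r[["k12"]]; G[2, 1] <- r[["k12"]]
      G[1, 2] <- r[["k21"]]; G[2, 2] <- -(r[["k21"]] + r[["k23"]])
      G[3, 2] <- r[["k23"]]
      G[2, 3] <- r[["k32"]]; G[3, 3] <- -r[["k32"]]
      # detailed balance chain: pi2/pi1 = k12/k21, pi3/pi2 = k23/k32
      w <- c(1, r[["k12"]] / r[["k21"]],
             r[["k12"]] / r[["k21"]] * r[["k23"]] / r[["k32"]])
      list(kind = kind, generator = G, stationary = w / sum(w))
    },
    biexp_trace = {
      tau <- opts$tau; if (is.null(tau)) tau <- c(5, 20)
      amps <- opts$amps; if (is.null(amps)) amps <- c(0.7, 0.3)
      dt <- opts$dt; if (is.null(dt)) dt <- 0.25
      t_end <- opts$t_end; if (is.null(t_end)) t_end <- 120
      tt <- seq(0, t_end, by = dt)
      y <- amps[1] * exp(-tt / tau[1]) + amps[2] * exp(-tt / tau[2])
      list(kind = kind, time = tt, y = y, tau = tau, amps = amps)
    },
    twocomp_camp = {
      g <- opts$g; if (is.null(g)) g <- 2e-6
      v <- opts$v; if (is.null(v)) v <- c(0.02, 0.678)
      # dc1 = g (c2 - c1)/v1 ; dc2 = g (c1 - c2)/v2
      A <- rbind(c(-g / v[1], g / v[1]),
                 c(g / v[2], -g / v[2]))
      lam <- -g * (1 / v[1] + 1 / v[2])
      list(kind = kind, A = A, v = v, g = g,
           relax_rate = -lam,
           equilibrium = function(c0) rep(sum(v * c0) / sum(v), 2))
    })
}
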