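#' Well-mixed receptor-ligand state
#'
#' A named numeric vector holding the five concentrations of the well-mixed
#' mass-action system: ligand `c`, bound/free normal receptors `R_b`, `R_f`
#' and bound/free decoy receptors `D_b`, `D_f`, all in consistent
#' per-volume units (dimensional or dimensionless; the kinetics are form
#' invariant, only the rate constants change).
#'
#' @param c ligand concentration
#' @param R_f,R_b free / bound normal receptor concentration
#' @param D_f,D_b free / bound decoy receptor concentration
#' @return named numeric vector of length 5 in canonical order
#' @export
wellmixed_state <- function(c, R_b = 0, R_f = 0, D_b = 0, D_f = 0) {
  s <- c(c = c, R_b = R_b, R_f = R_f, D_b = D_b, D_f = D_f)
  if (any(!is.finite(s))) stop("non-finite state component")
  s
}

#' Right-hand side of the well-mixed mass-action kinetics
#'
#' The ligand binds free normal receptors at rate `k_a1` (decoy: `k_a2`),
#' bound complexes dissociate at `k_d1` (`k_d2`) and are internalized at
#' `k_i1` (`k_i2`).  Internalization removes ligand from the system: the
#' net mass balance `d(c + R_b + D_b)/dt = -k_i1 R_b - k_i2 D_b` is
#' non-positive, and the receptor totals obey
#' `d(R_b + R_f)/dt = -k_i1 R_b`.
#'
#' @param state a [wellmixed_state()] vector (all components must be
#'   non-negative)
#' @param params any list carrying rate fields `k_a1`, `k_a2`, `k_d1`,
#'   `k_d2`, `k_i1`, `k_i2` in units matching the state (e.g. a
#'   [chamber_parameters()] or [nondimensionalize()] object)
#' @return named numeric vector of time derivatives, same order as the
#'   state
#' @export
wellmixed_rhs <- function(state, params) {
  if (any(state < 0)) stop("negative state component in well-mixed kinetics")
  c_ <- state[["c"]]; Rb <- state[["R_b"]]; Rf <- state[["R_f"]]
  Db <- state[["D_b"]]; Df <- state[["D_f"]]
  bind_r <- params$k_a1 * c_ * Rf
  bind_d <- params$k_a2 * c_ * Df
  rel_r <- params$k_d1 * Rb
  rel_d <- params$k_d2 * Db
  c(c = rel_r - bind_r + rel_d - bind_d,
    R_b = bind_r - (params$k_d1 + params$k_i1) * Rb,
    R_f = rel_r - bind_r,
    D_b = bind_d - (params$k_d2 + params$k_i2) * Db,
    D_f = rel_d - bind_d)
}

#' Integrate the well-mixed kinetics
#'
#' Adaptive high-order time integration of [wellmixed_rhs()] via
#' [deSolve::ode()].  Used for standalone kinetic studies and as the
#' reference trajectory in conservation and equilibrium checks.
#'
#' @param state0 initial [wellmixed_state()]
#' @param params rate-carrying parameter list (see [wellmixed_rhs()])
#' @param times output times
#' @param method integration method passed to [deSolve::ode()]
#' @param ... further arguments for [deSolve::ode()] (tolerances etc.)
#' @return a data.frame with columns `time`, `c`, `R_b`, `R_f`, `D_b`,
#'   `D_f`
#' @export
simulate_wellmixed <- function(state0, params, times, method = "lsoda", ...) {
  f <- function(t, y, p) list(wellmixed_rhs(y, p))
  out <- deSolve::ode(y = state0, times = times, func = f, parms = params,
                      method = method, ...)
  as.data.frame(out)
}

#' Equilibrium receptor occupancy at a frozen ligand level
#'
#' For a fixed dimensionless ligand concentration `c` the per-cell bound
#' occupancy of each receptor class relaxes to
#' \deqn{\rho^* = \frac{\tilde k_a c}{\tilde k_d + \tilde k_i -
#'   \tilde k_a c (\tilde\beta - 1)},}
#' with the class-specific rates and upregulation factor.  The denominator
#' must be positive; otherwise ligand-driven upregulation outruns
#' unbinding and the occupancy grows without bound.
#'
#' @param c_fixed dimensionless ligand concentration (>= 0)
#' @param dp a `chamber_dimensionless` parameter set
#' @return named vector `c(rho_r = ..., rho_d = ...)` of equilibrium
#'   occupancies (decoy entry is 0 when the decoy class is absent)
#' @export
wellmixed_equilibrium <- function(c_fixed, dp) {
  stopifnot(c_fixed >= 0)
  occ <- function(ka, kd, ki, up) {
    if (ka == 0) return(0)
    den <- kd + ki - ka * c_fixed * (up - 1)
    if (den <= 0)
      stop("non-positive denominator: unbounded upregulation regime")
    ka * c_fixed / den
  }
  c(rho_r = occ(dp$k_a1, dp$k_d1, dp$k_i1, dp$beta),
    rho_d = occ(dp$k_a2, dp$k_d2, dp$k_i2, dp$delta))
}

#' Free receptors implied by the upregulation closure
#'
#' Total receptors per cell grow with occupancy:
#' `R_b + R_f = Gamma_r (n + beta R_b)` for the normal class (decoy
#' analogue with `Gamma_d`, `delta`).  Given the cell density and the
#' per-cell bound occupancy this returns the free-receptor concentration.
#' For a dimensional parameter set (`rho` in mol/cell) this is
#' `Gamma (n + beta n rho) - n rho`; for a dimensionless set (`rho` scaled
#' by `Gamma`) it is `Gamma_tilde n (1 + (beta_tilde - 1) rho)` — the same
#' relation expressed in scaled variables.
#'
#' @param n cell density (>= 0)
#' @param rho per-cell bound receptor occupancy (>= 0); scaled by the
#'   receptor load when `params` is dimensionless
#' @param params [chamber_parameters()] or `chamber_dimensionless`
#' @param receptor `"normal"` or `"decoy"`
#' @return free receptor concentration (same unit system as the inputs)
#' @export
closure_free_receptors <- function(n, rho, params,
                                   receptor = c("normal", "decoy")) {
  receptor <- match.arg(receptor)
  stopifnot(all(n >= 0), all(rho >= 0))
  if (receptor == "normal") {
    G <- params$Gamma_r; up <- params$beta
  } else {
    G <- params$Gamma_d; up <- params$delta
  }
  if (inherits(params, "chamber_dimensionless")) {
    G * n * (1 + (up - 1) * rho)
  } else {
    G * (n + up * n * rho) - n * rho
  }
}

#' Convert between concentration and per-cell occupancy views
#'
#' The spatial solver tracks per-cell occupancies `rho = bound / n`
#' (scaled by the receptor load in dimensionless form), while conservation
#' arguments are natural in the bound-concentration view.  These helpers
#' convert a bound concentration to an occupancy and back.
#'
#' @param bound bound receptor concentration
#' @param n cell density (> 0)
#' @param Gamma receptor load used for scaling (1 for the unscaled
#'   dimensional occupancy)
#' @return `occupancy_from_bound`: per-cell occupancy; `bound_from_occupancy`:
#'   bound concentration
#' @export
occupancy_from_bound <- function(bound, n, Gamma = 1) {
  stopifnot(all(n > 0), Gamma > 0)
  bound / (n * Gamma)
}

#' @rdname occupancy_from_bound
#' @param rho per-cell occupancy
#' @export
bound_from_occupancy <- function(rho, n, Gamma = 1) {
  rho * n * Gamma
}
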