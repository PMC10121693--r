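#' Dimensional model parameters for the Boyden-chamber migration model
#'
#' Constructs the full set of dimensional quantities governing the
#' four-field chemotaxis model: cell motility, ligand diffusivity,
#' chemo-attractant/-repellent coefficients, the mass-action rate constants
#' of the normal (CD95) and decoy (DcR3) receptor classes, the receptor
#' upregulation rates, the chamber geometry, and the initial loading of the
#' two wells.  Defaults are the literature/estimated values used throughout
#' the package; any subset can be overridden.
#'
#' Units: lengths in cm, times in s, ligand concentration in an opaque
#' "ligand-unit" per cm^3 (only the products `k_a * T * c0` enter the
#' dimensionless dynamics, so no molar-mass conversion is ever needed),
#' receptor loads `Gamma_r`, `Gamma_d` in mol per cell, cell density in
#' cells per cm^3.
#'
#' The upregulation rates `beta` and `delta` default to `0.97 / Gamma_r`
#' and `0.952 / Gamma_d`, i.e. dimensionless upregulation factors 0.97 and
#' 0.952; values of `beta * Gamma_r` or `delta * Gamma_d` at or above 1
#' put the receptor closure in the unbounded-growth regime and are flagged
#' by [validate_parameters()].
#'
#' @param D_n cell random motility (cm^2/s)
#' @param D_c ligand diffusivity (cm^2/s)
#' @param chi chemo-attractant coefficient (cm^2/(s mol))
#' @param mu chemo-repellent coefficient (cm^2/(s mol))
#' @param k_a1,k_a2 association rates, normal/decoy (cm^3/(s ligand-unit))
#' @param k_d1,k_d2 dissociation rates, normal/decoy (1/s)
#' @param k_i1,k_i2 internalization rates, normal/decoy (1/s)
#' @param beta,delta receptor upregulation rates (1/mol)
#' @param Gamma_r,Gamma_d free normal/decoy receptor load per cell (mol)
#' @param L cell diameter (cm)
#' @param L_u,L_f,L_l heights of upper well, filter, lower well (cm)
#' @param n0 initial upper-well cell density (cells/cm^3)
#' @param c0 initial lower-well ligand concentration (ligand-unit/cm^3)
#' @param T_scale time scale used for non-dimensionalization (s)
#' @return an object of class `chamber_parameters` (a named list)
#' @seealso [validate_parameters()], [nondimensionalize()]
#' @examples
#' p <- chamber_parameters()
#' validate_parameters(p)
#' nondimensionalize(p)
#' @export
chamber_parameters <- function(D_n = 1.3e-10,
                               D_c = 7.3e-6,
                               chi = 2e12,
                               mu = 1e10,
                               k_a1 = 1.67e7,
                               k_a2 = 8.33e7,
                               k_d1 = 0.0058,
                               k_d2 = 0.0029,
                               k_i1 = 0.004,
                               k_i2 = 8e-4,
                               Gamma_r = 4.98e-21,
                               Gamma_d = 3.984e-21,
                               beta = 0.97 / Gamma_r,
                               delta = if (Gamma_d > 0) 0.952 / Gamma_d else 0,
                               L = 9.2e-4,
                               L_u = 0.0375,
                               L_f = 0.015,
                               L_l = 0.03125,
                               n0 = 4e5,
                               c0 = 6e-8,
                               T_scale = 3600) {
  p <- list(D_n = D_n, D_c = D_c, chi = chi, mu = mu,
            k_a1 = k_a1, k_a2 = k_a2, k_d1 = k_d1, k_d2 = k_d2,
            k_i1 = k_i1, k_i2 = k_i2,
            beta = beta, delta = delta,
            Gamma_r = Gamma_r, Gamma_d = Gamma_d,
            L = L, L_u = L_u, L_f = L_f, L_l = L_l,
            n0 = n0, c0 = c0, T_scale = T_scale)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  class(p) <- "chamber_parameters"
  p
}

# fields that may legally be zero (the no-decoy limit)
.zero_ok_fields <- c("beta", "delta", "mu", "Gamma_d",
                     "k_a2", "k_d2", "k_i2")

#' Validate a dimensional parameter set
#'
#' Checks the admissibility rules of the model: strict positivity of every
#' quantity except the decoy-side ones (`mu`, `delta`, `Gamma_d`, `k_a2`,
#' `k_d2`, `k_i2`) and `beta`, which may be zero in the no-decoy limit;
#' bounded receptor upregulation (`beta * Gamma_r <= 1`,
#' `delta * Gamma_d <= 1`); and a cell diameter smaller than the filter
#' thickness.  Violations are returned as diagnostics, not raised.
#'
#' @param params a [chamber_parameters()] object
#' @return character vector of violation descriptions; empty if all
#'   invariants hold
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "chamber_parameters"))
  bad <- character(0)
  for (nm in setdiff(names(unclass(params)), .zero_ok_fields)) {
    if (params[[nm]] <= 0)
      bad <- c(bad, paste0(nm, ": must be strictly positive"))
  }
  for (nm in .zero_ok_fields) {
    if (params[[nm]] < 0)
      bad <- c(bad, paste0(nm, ": must be non-negative"))
  }
  if (params$beta * params$Gamma_r > 1)
    bad <- c(bad, "beta: beta * Gamma_r exceeds 1 (unbounded receptor upregulation)")
  if (params$delta * params$Gamma_d > 1)
    bad <- c(bad, "delta: delta * Gamma_d exceeds 1 (unbounded receptor upregulation)")
  if (params$L >= params$L_f)
    bad <- c(bad, "L: cell diameter must be smaller than the filter thickness L_f")
  bad
}

#' Non-dimensionalize a parameter set
#'
#' Maps the dimensional parameters to the dimensionless set in which the
#' spatial system is actually solved.  Length is scaled by the filter
#' thickness `L_f`, time by `T_scale`, cell density by `n0`, ligand by
#' `c0`, and per-cell receptor occupancies by `Gamma_r` (normal) and
#' `Gamma_d` (decoy).  Explicitly:
#' \deqn{\tilde D_n = D_n T/L_f^2,\quad \tilde\chi = \chi T \Gamma_r/L_f^2,
#'   \quad \tilde\mu = \mu T \Gamma_d/L_f^2,\quad \tilde D_c = D_c T/L_f^2,}
#' \deqn{\tilde k_{a} = k_{a} T c_0,\quad \tilde k_{d} = k_{d} T,\quad
#'   \tilde k_{i} = k_{i} T,}
#' \deqn{\tilde\Gamma_r = \Gamma_r n_0/c_0,\quad
#'   \tilde\Gamma_d = \Gamma_d n_0/c_0,\quad \tilde\beta = \beta\Gamma_r,
#'   \quad \tilde\delta = \delta\Gamma_d,}
#' and the geometric ratios `L/L_f`, `L_u/L_f`, `L_l/L_f`.
#'
#' @param params a validated [chamber_parameters()] object
#' @return an object of class `chamber_dimensionless`: the tilde parameter
#'   set, carrying the scales used as attribute `"scales"` so the mapping
#'   can be inverted exactly
#' @export
nondimensionalize <- function(params) {
  viol <- validate_parameters(params)
  if (length(viol))
    stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "))
  Lf2 <- params$L_f^2
  Tt <- params$T_scale
  dp <- list(
    D_n  = params$D_n * Tt / Lf2,
    D_c  = params$D_c * Tt / Lf2,
    chi  = params$chi * Tt * params$Gamma_r / Lf2,
    mu   = params$mu * Tt * params$Gamma_d / Lf2,
    k_a1 = params$k_a1 * Tt * params$c0,
    k_a2 = params$k_a2 * Tt * params$c0,
    k_d1 = params$k_d1 * Tt,
    k_d2 = params$k_d2 * Tt,
    k_i1 = params$k_i1 * Tt,
    k_i2 = params$k_i2 * Tt,
    Gamma_r = params$Gamma_r * params$n0 / params$c0,
    Gamma_d = params$Gamma_d * params$n0 / params$c0,
    beta  = params$beta * params$Gamma_r,
    delta = params$delta * params$Gamma_d,
    L   = params$L / params$L_f,
    L_u = params$L_u / params$L_f,
    L_l = params$L_l / params$L_f
  )
  attr(dp, "scales") <- list(L_f = params$L_f, T_scale = Tt,
                             n0 = params$n0, c0 = params$c0,
                             Gamma_r = params$Gamma_r,
                             Gamma_d = params$Gamma_d)
  class(dp) <- "chamber_dimensionless"
  dp
}

# Invert nondimensionalize() using the scales stored on the object.
# Exact arithmetic inverse of the tilde formulas; used for round-trip checks
# and for reporting.
redimensionalize <- function(dp) {
  stopifnot(inherits(dp, "chamber_dimensionless"))
  s <- attr(dp, "scales")
  Lf2 <- s$L_f^2
  Tt <- s$T_scale
  chamber_parameters(
    D_n  = dp$D_n * Lf2 / Tt,
    D_c  = dp$D_c * Lf2 / Tt,
    chi  = if (s$Gamma_r > 0) dp$chi * Lf2 / (Tt * s$Gamma_r) else 0,
    mu   = if (s$Gamma_d > 0) dp$mu * Lf2 / (Tt * s$Gamma_d) else 0,
    k_a1 = dp$k_a1 / (Tt * s$c0),
    k_a2 = dp$k_a2 / (Tt * s$c0),
    k_d1 = dp$k_d1 / Tt,
    k_d2 = dp$k_d2 / Tt,
    k_i1 = dp$k_i1 / Tt,
    k_i2 = dp$k_i2 / Tt,
    Gamma_r = s$Gamma_r,
    Gamma_d = s$Gamma_d,
    beta  = if (s$Gamma_r > 0) dp$beta / s$Gamma_r else 0,
    delta = if (s$Gamma_d > 0) dp$delta / s$Gamma_d else 0,
    L   = dp$L * s$L_f,
    L_u = dp$L_u * s$L_f,
    L_l = dp$L_l * s$L_f,
    n0 = s$n0, c0 = s$c0, T_scale = Tt
  )
}

#' Explicit-stability indicator for the ligand diffusion term
#'
#' The forward Euler scheme is stable for the stiff ligand-diffusion term
#' only if `dt <= h^2 / (2 * D_c_tilde)`.  This helper reports the ratio
#' `dt * D_c_tilde / h^2`; values above 0.5 violate the bound.
#'
#' @param dp a `chamber_dimensionless` object
#' @param h grid spacing (filter-thickness units)
#' @param dt time step (hours)
#' @return the dimensionless stability ratio
#' @export
diffusion_stability_ratio <- function(dp, h, dt) {
  stopifnot(inherits(dp, "chamber_dimensionless"), h > 0, dt > 0)
  dt * dp$D_c / h^2
}

#' @export
print.chamber_parameters <- function(x, ...) {
  cat("Boyden-chamber model parameters (dimensional)\n")
  v <- unlist(unclass(x))
  for (nm in names(v)) cat(sprintf("  %-8s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' @export
print.chamber_dimensionless <- function(x, ...) {
  cat("Boyden-chamber model parameters (dimensionless)\n")
  v <- unlist(unclass(x))
  for (nm in names(v)) cat(sprintf("  %-8s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Set the no-decoy limit of a parameter set
#'
#' Returns a copy of `params` with every decoy-receptor quantity
#' (`Gamma_d`, `mu`, `delta`, `k_a2`, `k_d2`, `k_i2`) set to zero.  With a
#' zero initial decoy occupancy this makes the decoy field identically
#' zero, so the full system collapses to the reduced three-field system.
#'
#' @param params a [chamber_parameters()] object
#' @return a `chamber_parameters` object in the no-decoy limit
#' @export
without_decoy <- function(params) {
  stopifnot(inherits(params, "chamber_parameters"))
  params$Gamma_d <- 0
  params$mu <- 0
  params$delta <- 0
  params$k_a2 <- 0
  params$k_d2 <- 0
  params$k_i2 <- 0
  params
}
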