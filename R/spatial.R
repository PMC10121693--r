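#' Initial state of the in-silico Boyden-chamber assay
#'
#' Cells are loaded in the upper well and enter the filter at its upper
#' face: the dimensionless cell density is zero on the filter except
#' `n = 1` at the `x = 1` node.  Ligand fills the lower well, `c = 1` for
#' `x <= 0` (including the interface node) and zero elsewhere.  Both
#' per-cell occupancy fields start at zero.
#'
#' @param grid a [build_grid()] object
#' @param dp the matching `chamber_dimensionless` parameters
#' @return an object of class `chamber_state`: fields `n`, `rho_r`,
#'   `rho_d` on the filter nodes, `c` on the full chamber, and time `t`
#'   (hours)
#' @export
initial_state <- function(grid, dp) {
  stopifnot(inherits(grid, "chamber_grid"))
  nf <- length(grid$filter_idx)
  n <- numeric(nf)
  n[nf] <- 1
  c_ <- as.numeric(grid$x <= 0)
  st <- list(n = n, c = c_, rho_r = numeric(nf), rho_d = numeric(nf), t = 0)
  class(st) <- "chamber_state"
  st
}

# second-order gradient on the filter nodes: central in the interior,
# one-sided at the faces
grad_face <- function(f, h) {
  m <- length(f)
  g <- numeric(m)
  g[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  if (m > 2) g[2:(m - 1)] <- (f[3:m] - f[1:(m - 2)]) / (2 * h)
  g[m] <- (3 * f[m] - 4 * f[m - 1] + f[m - 2]) / (2 * h)
  g
}

# gradient with zero-gradient mirror ghosts at the filter faces
grad_ghost <- function(f, h) {
  m <- length(f)
  g <- numeric(m)
  if (m > 2) g[2:(m - 1)] <- (f[3:m] - f[1:(m - 2)]) / (2 * h)
  g
}

#' Cell flux through the filter
#'
#' The transport law combines random motility down the cell-density
#' gradient, attraction up the bound-normal-receptor gradient and
#' repulsion up the bound-decoy-receptor gradient:
#' `K_n = -D_n n_x + chi n rho_r_x - mu n rho_d_x` (dimensionless).
#' Gradients are central differences at interior nodes and one-sided
#' second-order differences at the filter faces.
#'
#' @param n,rho_r,rho_d fields on the filter nodes
#' @param dp `chamber_dimensionless` parameters
#' @param grid a [build_grid()] object
#' @return the flux `K_n` on the filter nodes
#' @export
cell_flux <- function(n, rho_r, rho_d, dp, grid) {
  h <- grid$h
  -dp$D_n * grad_face(n, h) + dp$chi * n * grad_face(rho_r, h) -
    dp$mu * n * grad_face(rho_d, h)
}

.rho_advection_eps <- 1e-12

#' Right-hand side of the spatial system
#'
#' Reference (pure R) evaluation of the semi-discrete system: the cell
#' continuity equation with reservoir-exchange boundary rows
#' (`dn/dt = -K_n/L` at `x = 0`, `+K_n/L` at `x = 1`), ligand diffusion on
#' the whole chamber with mass-action exchange terms on the filter and
#' no-flux mirror ghosts at the chamber ends, and the per-cell occupancy
#' equations with advection at velocity `K_n / n` (skipped where
#' `n < 1e-12`: occupancy is a per-cell quantity, undefined without
#' cells).  The compiled stepper evaluates the identical discretization;
#' the two are cross-checked in the tests.
#'
#' @param state a `chamber_state`
#' @param dp `chamber_dimensionless` parameters
#' @param grid a [build_grid()] object
#' @param reduced if `TRUE`, evaluate the reduced no-decoy three-field
#'   system (the decoy occupancy derivative is returned as zero)
#' @return list of derivative fields `dn`, `dc`, `drho_r`, `drho_d` and
#'   the flux `K_n`
#' @export
rhs_spatial <- function(state, dp, grid, reduced = FALSE) {
  h <- grid$h
  n <- state$n; c_ <- state$c; rr <- state$rho_r; rd <- state$rho_d
  m <- length(n)
  if (reduced) {
    K <- -dp$D_n * grad_face(n, h) + dp$chi * n * grad_face(rr, h)
  } else {
    K <- cell_flux(n, rr, rd, dp, grid)
  }

  dn <- numeric(m)
  dn[1] <- -K[1] / dp$L
  dn[m] <- K[m] / dp$L
  if (m > 2) dn[2:(m - 1)] <- -(K[3:m] - K[1:(m - 2)]) / (2 * h)

  N <- grid$n_total
  lap <- numeric(N)
  lap[1] <- 2 * (c_[2] - c_[1])
  lap[2:(N - 1)] <- c_[3:N] - 2 * c_[2:(N - 1)] + c_[1:(N - 2)]
  lap[N] <- 2 * (c_[N - 1] - c_[N])
  dc <- dp$D_c * lap / h^2

  cf <- c_[grid$filter_idx]
  A <- 1 + (dp$beta - 1) * rr
  reac <- dp$k_d1 * dp$Gamma_r * n * rr - dp$k_a1 * cf * n * dp$Gamma_r * A
  if (!reduced) {
    B <- 1 + (dp$delta - 1) * rd
    reac <- reac + dp$k_d2 * dp$Gamma_d * n * rd -
      dp$k_a2 * cf * n * dp$Gamma_d * B
  }
  dc[grid$filter_idx] <- dc[grid$filter_idx] + reac

  v <- ifelse(n >= .rho_advection_eps, K / pmax(n, .rho_advection_eps), 0)
  drr <- -v * grad_ghost(rr, h) + dp$k_a1 * cf * A - (dp$k_d1 + dp$k_i1) * rr
  if (reduced) {
    drd <- numeric(m)
  } else {
    drd <- -v * grad_ghost(rd, h) + dp$k_a2 * cf * B - (dp$k_d2 + dp$k_i2) * rd
  }
  if (any(!is.finite(dn)) || any(!is.finite(dc)) ||
      any(!is.finite(drr)) || any(!is.finite(drd))) {
    bad <- which(!is.finite(c(dn, dc, drr, drd)))[1]
    stop("non-finite derivative (flat index ", bad, ") at t = ", state$t)
  }
  list(dn = dn, dc = dc, drho_r = drr, drho_d = drd, K_n = K)
}

#' Advance one forward Euler step
#'
#' `y + dt * rhs(y)`, followed by clipping of tiny negative values
#' (`[-1e-10, 0)`) to zero.  The step size must respect the explicit
#' diffusion stability bound `dt <= h^2 / (2 D_c)` unless
#' `override_stability = TRUE`.
#'
#' @param state a `chamber_state`
#' @param dp,grid as in [rhs_spatial()]
#' @param dt time step (hours)
#' @param reduced evaluate the no-decoy system
#' @param override_stability allow a step size beyond the diffusion bound
#' @return the state at `t + dt` (attribute `"clipped"` counts clipped
#'   entries)
#' @export
step_euler <- function(state, dp, grid, dt, reduced = FALSE,
                       override_stability = FALSE) {
  if (!override_stability && diffusion_stability_ratio(dp, grid$h, dt) > 0.5)
    stop("dt = ", dt, " violates the explicit stability bound h^2/(2 D_c) = ",
         grid$h^2 / (2 * dp$D_c), "; pass override_stability = TRUE to force")
  d <- rhs_spatial(state, dp, grid, reduced = reduced)
  out <- state
  out$n <- state$n + dt * d$dn
  out$c <- state$c + dt * d$dc
  out$rho_r <- state$rho_r + dt * d$drho_r
  out$rho_d <- state$rho_d + dt * d$drho_d
  out$t <- state$t + dt
  clipped <- 0L
  for (f in c("n", "c", "rho_r", "rho_d")) {
    neg <- out[[f]] < 0
    if (any(neg)) {
      if (min(out[[f]]) < -1e-10)
        stop("field ", f, " dropped below -1e-10 (", min(out[[f]]), ")")
      clipped <- clipped + sum(neg)
      out[[f]][neg] <- 0
    }
  }
  attr(out, "clipped") <- clipped
  out
}

#' Advance one IMEX step (Crank-Nicolson ligand diffusion)
#'
#' Treats the stiff ligand-diffusion term implicitly (trapezoidal /
#' Crank-Nicolson; set `be = TRUE` for a backward Euler startup step) and
#' every advection and reaction term, as well as the `n`, `rho_r`, `rho_d`
#' updates, explicitly.  Converges to the forward Euler solution as
#' `dt -> 0` while remaining stable at step sizes far beyond the explicit
#' diffusion bound.
#'
#' @inheritParams step_euler
#' @param be use backward Euler for the diffusion half (startup smoothing)
#' @return the state at `t + dt`
#' @export
step_imex <- function(state, dp, grid, dt, reduced = FALSE, be = FALSE) {
  stopifnot(dt <= 1e-3)
  d <- rhs_spatial(state, dp, grid, reduced = reduced)
  # strip the diffusion part of dc; keep the reaction part
  N <- grid$n_total
  c_ <- state$c
  lap <- numeric(N)
  lap[1] <- 2 * (c_[2] - c_[1])
  lap[2:(N - 1)] <- c_[3:N] - 2 * c_[2:(N - 1)] + c_[1:(N - 2)]
  lap[N] <- 2 * (c_[N - 1] - c_[N])
  dc_react <- d$dc - dp$D_c * lap / grid$h^2

  theta <- if (be) 1 else 0.5
  lam_im <- theta * dt * dp$D_c / grid$h^2
  lam_ex <- (1 - theta) * dt * dp$D_c / grid$h^2
  b <- c_ + lam_ex * lap + dt * dc_react
  # tridiagonal (I - lam_im * S) with mirror-ghost doubled end couplings
  main <- rep(1 + 2 * lam_im, N)
  sub <- c(rep(-lam_im, N - 2), -2 * lam_im)
  sup <- c(-2 * lam_im, rep(-lam_im, N - 2))
  A <- diag(main)
  A[cbind(2:N, 1:(N - 1))] <- sub
  A[cbind(1:(N - 1), 2:N)] <- sup
  c_new <- solve(A, b)

  out <- state
  out$n <- state$n + dt * d$dn
  out$c <- as.numeric(c_new)
  out$rho_r <- state$rho_r + dt * d$drho_r
  out$rho_d <- state$rho_d + dt * d$drho_d
  out$t <- state$t + dt
  for (f in c("n", "c", "rho_r", "rho_d")) out[[f]] <- pmax(out[[f]], 0)
  out
}
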