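dp0 <- nondimensionalize(chamber_parameters())
g0 <- build_grid(dp0, h = 0.02)

test_that("the assay initial condition loads the wells as specified", {
  st <- initial_state(g0, dp0)
  nf <- length(g0$filter_idx)
  # only the x=1 node carries cells: trapezoid integral is h/2
  expect_equal(decoychemo:::trapz_filter(st$n, g0$h), g0$h / 2)
  expect_equal(st$n[nf], 1)
  expect_equal(sum(st$n > 0), 1L)
  # ligand fills the lower well up to and including x=0
  expect_equal(st$c[1], 1)                       # x = -L_l
  expect_equal(st$c[g0$i0], 1)                   # x = 0
  expect_equal(st$c[g0$i0 + 1L], 0)              # first node inside filter
  expect_equal(st$c[g0$n_total], 0)              # x = 1 + L_u
  expect_true(all(st$rho_r == 0) && all(st$rho_d == 0))
  expect_equal(st$t, 0)
})

test_that("the cell flux matches its transport law on simple profiles", {
  nf <- length(g0$filter_idx)
  x <- (seq_len(nf) - 1) * g0$h
  ones <- rep(1, nf)
  # uniform fields carry no flux
  expect_equal(cell_flux(ones, ones * 0.3, ones * 0.1, dp0, g0), rep(0, nf))
  # unit attractant gradient: K = chi everywhere (one-sided stencils are
  # exact for linear profiles)
  expect_equal(cell_flux(ones, x, ones * 0.1, dp0, g0), rep(dp0$chi, nf))
  # pure diffusion of a linear cell profile: K = D_n
  expect_equal(cell_flux(1 - x, ones * 0.3, ones * 0.3, dp0, g0),
               rep(dp0$D_n, nf))
  # unit repellent gradient: K = -mu
  expect_equal(cell_flux(ones, ones * 0.3, x, dp0, g0), rep(-dp0$mu, nf))
})

test_that("the spatial right-hand side behaves at its fixed points", {
  st <- initial_state(g0, dp0)
  zero <- st
  zero$n[] <- 0; zero$c[] <- 0
  d <- rhs_spatial(zero, dp0, g0)
  expect_equal(d$dn, rep(0, length(zero$n)))
  expect_equal(d$dc, rep(0, length(zero$c)))
  expect_equal(d$drho_r, rep(0, length(zero$n)))
  expect_equal(d$drho_d, rep(0, length(zero$n)))

  # without cells the reaction terms vanish and occupancies load at rate
  # k_a1 c (k_a2 c for the decoy class)
  nocell <- st
  nocell$n[] <- 0
  d <- rhs_spatial(nocell, dp0, g0)
  cf <- nocell$c[g0$filter_idx]
  expect_equal(d$drho_r, dp0$k_a1 * cf)
  expect_equal(d$drho_d, dp0$k_a2 * cf)
  lap <- c(2 * (nocell$c[2] - nocell$c[1]),
           diff(nocell$c, differences = 2),
           2 * (nocell$c[g0$n_total - 1] - nocell$c[g0$n_total]))
  expect_equal(d$dc, dp0$D_c * lap / g0$h^2)
})

test_that("the R reference and compiled right-hand sides agree", {
  for (seed in 1:5) {
    st <- random_state(g0, seed)
    d_r <- rhs_spatial(st, dp0, g0)
    d_c <- decoychemo:::cpp_rhs_full(st$n, st$c, st$rho_r, st$rho_d,
                                     par_vec_of(dp0), grid_info(g0))
    expect_equal(d_c$dn, d_r$dn, tolerance = 1e-12)
    expect_equal(d_c$dc, d_r$dc, tolerance = 1e-12)
    expect_equal(d_c$drho_r, d_r$drho_r, tolerance = 1e-12)
    expect_equal(d_c$drho_d, d_r$drho_d, tolerance = 1e-12)
    expect_equal(d_c$K_n, d_r$K_n, tolerance = 1e-12)
  }
})

test_that("zeroed decoy machinery reduces the RHS to the three-field system", {
  dpz <- dp0
  dpz$Gamma_d <- 0; dpz$mu <- 0
  dpz$k_a2 <- 0; dpz$k_d2 <- 0; dpz$k_i2 <- 0; dpz$delta <- 0
  for (seed in 1:3) {
    st <- random_state(g0, seed)
    st$rho_d[] <- 0
    d_full <- rhs_spatial(st, dpz, g0, reduced = FALSE)
    d_red <- rhs_spatial(st, dpz, g0, reduced = TRUE)
    expect_identical(d_full$dn, d_red$dn)
    expect_identical(d_full$dc, d_red$dc)
    expect_identical(d_full$drho_r, d_red$drho_r)
    expect_equal(d_full$drho_d, rep(0, length(st$n)))
  }
})

test_that("explicit stepping conserves ligand and respects its bound", {
  dpz <- kinetics_off(dp0)
  st <- initial_state(g0, dpz)
  expect_error(step_euler(st, dpz, g0, dt = 1e-3), "stability")
  s1 <- step_euler(st, dpz, g0, dt = 1e-6)
  expect_equal(decoychemo:::trapz_chamber(s1$c, g0$h),
               decoychemo:::trapz_chamber(st$c, g0$h), tolerance = 1e-14)
  expect_equal(s1$t, 1e-6)
  # IMEX step conserves too, at a step far beyond the explicit bound
  s2 <- step_imex(st, dpz, g0, dt = 5e-4)
  expect_equal(decoychemo:::trapz_chamber(s2$c, g0$h),
               decoychemo:::trapz_chamber(st$c, g0$h), tolerance = 1e-12)
})

test_that("one compiled step equals one R step", {
  st <- random_state(g0, 7)
  # euler
  out <- decoychemo:::cpp_advance(st$n, st$c, st$rho_r, st$rho_d,
                                  st$n * 0, st$c * 0, st$n * 0, st$n * 0,
                                  -1L, par_vec_of(dp0), grid_info(g0),
                                  1e-6, 1L, 0L, "euler", 0L, 1e-10, 0L)
  sr <- step_euler(st, dp0, g0, dt = 1e-6)
  expect_equal(out$n, sr$n, tolerance = 1e-14)
  expect_equal(out$c, sr$c, tolerance = 1e-14)
  expect_equal(out$rho_r, sr$rho_r, tolerance = 1e-14)
  expect_equal(out$rho_d, sr$rho_d, tolerance = 1e-14)
  # imex (past the Rannacher startup so both use Crank-Nicolson); the
  # state keeps n away from zero so one explicit step stays admissible
  st$n <- st$n + 0.5
  out <- decoychemo:::cpp_advance(st$n, st$c, st$rho_r, st$rho_d,
                                  st$n * 0, st$c * 0, st$n * 0, st$n * 0,
                                  -1L, par_vec_of(dp0), grid_info(g0),
                                  1e-5, 1L, 10L, "imex", 4L, 1e-10, 0L)
  si <- step_imex(st, dp0, g0, dt = 1e-5)
  expect_equal(out$c, si$c, tolerance = 1e-10)
  expect_equal(out$n, si$n, tolerance = 1e-13)
})

test_that("with all transport off the cell profile never moves", {
  dpz <- dp0
  dpz$chi <- 0; dpz$mu <- 0; dpz$D_n <- 0
  sim <- simulate_dimensionless(dpz, h = 0.04, dt = 2e-4, t_max = 0.5,
                                snapshot_times = numeric(0))
  st0 <- initial_state(sim$grid, dpz)
  expect_equal(sim$final_state$n, st0$n)
})

test_that("repeated runs are bit-for-bit identical", {
  a <- fast_run(default_params(), t_max = 0.5)
  b <- fast_run(default_params(), t_max = 0.5)
  expect_identical(a$series, b$series)
  expect_identical(a$final_state, b$final_state)
})

test_that("euler time stepping is first order on the diffusion subproblem", {
  # smooth cosine mode on a small chamber; the semi-discrete solution is
  # known in closed form, so the remaining error is purely temporal
  p <- chamber_parameters(L_u = 1, L_f = 1, L_l = 1, L = 0.5)
  dp <- kinetics_off(nondimensionalize(p))
  dp$D_c <- 1; dp$chi <- 0; dp$mu <- 0; dp$D_n <- 0
  g <- build_grid(dp, h = 0.1)
  x <- g$x
  Ltot <- x[length(x)] - x[1]
  k <- pi / Ltot
  c0 <- 1 + cos(k * (x - x[1]))   # shifted mode, stays non-negative
  lam_d <- dp$D_c * 2 * (1 - cos(k * g$h)) / g$h^2   # discrete decay rate
  t_end <- 0.2
  err_t <- sapply(c(2e-3, 1e-3, 5e-4), function(dt) {
    st <- initial_state(g, dp)
    st$n[] <- 0; st$c <- c0
    for (i in seq_len(round(t_end / dt)))
      st <- step_euler(st, dp, g, dt, override_stability = TRUE)
    max(abs(st$c - (1 + (c0 - 1) * exp(-lam_d * t_end))))
  })
  orders <- log2(err_t[-length(err_t)] / err_t[-1])
  expect_true(all(orders > 0.8 & orders < 1.2))
})

test_that("the spatial stencil is second order on the diffusion subproblem", {
  p <- chamber_parameters(L_u = 1, L_f = 1, L_l = 1, L = 0.5)
  t_end <- 0.1
  err_h <- sapply(c(0.2, 0.1, 0.05), function(h) {
    dp <- kinetics_off(nondimensionalize(p))
    dp$D_c <- 1; dp$chi <- 0; dp$mu <- 0; dp$D_n <- 0
    g <- build_grid(dp, h = h)
    x <- g$x
    Ltot <- x[length(x)] - x[1]
    k <- pi / Ltot
    st <- initial_state(g, dp)
    st$n[] <- 0
    st$c <- 1 + cos(k * (x - x[1]))
    # Crank-Nicolson stepping so the temporal error cannot mask the
    # spatial one
    dt <- 1e-3
    for (i in seq_len(round(t_end / dt)))
      st <- step_imex(st, dp, g, dt)
    max(abs(st$c - (1 + cos(k * (x - x[1])) * exp(-dp$D_c * k^2 * t_end))))
  })
  orders <- log2(err_h[-length(err_h)] / err_h[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("Crank-Nicolson diffusion is second order in the step size", {
  p <- chamber_parameters(L_u = 1, L_f = 1, L_l = 1, L = 0.5)
  dp <- kinetics_off(nondimensionalize(p))
  dp$D_c <- 1; dp$chi <- 0; dp$mu <- 0; dp$D_n <- 0
  g <- build_grid(dp, h = 0.1)
  x <- g$x
  k <- pi / (x[length(x)] - x[1])
  c0 <- 1 + cos(k * (x - x[1]))
  lam_d <- dp$D_c * 2 * (1 - cos(k * g$h)) / g$h^2
  t_end <- 0.2
  err_t <- sapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    st <- initial_state(g, dp)
    st$n[] <- 0; st$c <- c0
    for (i in seq_len(round(t_end / dt)))
      st <- step_imex(st, dp, g, dt)
    max(abs(st$c - (1 + (c0 - 1) * exp(-lam_d * t_end))))
  })
  orders <- log2(err_t[-length(err_t)] / err_t[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("the upwind fallback tracks the central scheme and permits fine grids", {
  p <- default_params()
  ctr <- simulate_chamber(p, t_max = 1, snapshot_times = numeric(0))
  upw <- simulate_chamber(p, t_max = 1, snapshot_times = numeric(0),
                          advection = "upwind")
  # first-order advection smears the front but preserves the physics
  expect_lt(abs(final_nf(upw) - final_nf(ctr)) / final_nf(ctr), 0.35)
  # a grid on which the central scheme loses positivity runs clean upwind
  fine <- simulate_chamber(p, h = 0.01, dt = 2.5e-5, t_max = 0.5,
                           snapshot_times = numeric(0), advection = "upwind")
  expect_true(all(fine$final_state$n >= 0))
  expect_error(
    simulate_chamber(p, h = 0.01, dt = 2.5e-5, t_max = 0.5,
                     snapshot_times = numeric(0)),
    "dropped below")
})
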