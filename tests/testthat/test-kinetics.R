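test_that("well-mixed derivatives obey the mass-action bookkeeping", {
  p <- default_params()
  # no ligand and no bound complexes: nothing moves
  d0 <- wellmixed_rhs(wellmixed_state(c = 0, R_f = 2, D_f = 3), p)
  expect_equal(unname(d0), rep(0, 5))

  # structural identities on random non-negative states (O(1) rates so
  # the identities are not masked by catastrophic cancellation)
  q <- list(k_a1 = 1.3, k_d1 = 0.4, k_i1 = 0.2,
            k_a2 = 0.8, k_d2 = 0.3, k_i2 = 0.1)
  set.seed(42)
  ok <- logical(0)
  for (k in 1:20) {
    s <- wellmixed_state(c = runif(1), R_b = runif(1), R_f = runif(1),
                         D_b = runif(1), D_f = runif(1))
    d <- wellmixed_rhs(s, q)
    ok <- c(ok,
            abs(d[["R_b"]] + d[["R_f"]] + q$k_i1 * s[["R_b"]]) < 1e-14,
            abs(d[["D_b"]] + d[["D_f"]] + q$k_i2 * s[["D_b"]]) < 1e-14,
            abs(d[["c"]] + d[["R_b"]] + d[["D_b"]] +
                  q$k_i1 * s[["R_b"]] + q$k_i2 * s[["D_b"]]) < 1e-14,
            d[["R_b"]] + d[["R_f"]] <= 0)   # receptor totals only decay
  }
  expect_true(all(ok))

  # dimensionless rates: c=1, R_f=1, everything else empty
  dp <- nondimensionalize(p)
  d <- wellmixed_rhs(wellmixed_state(c = 1, R_f = 1), dp)
  expect_equal(d[["R_b"]], dp$k_a1)
  expect_equal(d[["c"]], -dp$k_a1)

  expect_error(wellmixed_rhs(c(c = -1, R_b = 0, R_f = 0, D_b = 0, D_f = 0), p),
               "negative")
})

test_that("trajectories conserve ligand+complex totals without internalization", {
  p <- default_params(k_i1 = 1e-12, k_i2 = 1e-12)
  p$k_i1 <- 0; p$k_i2 <- 0
  dp <- nondimensionalize(default_params())
  dp$k_i1 <- 0; dp$k_i2 <- 0
  s0 <- wellmixed_state(c = 1, R_b = 0.1, R_f = 0.5, D_b = 0.05, D_f = 0.4)
  tr <- simulate_wellmixed(s0, dp, times = seq(0, 5, by = 0.25),
                           rtol = 1e-10, atol = 1e-12)
  tot_c <- tr$c + tr$R_b + tr$D_b
  tot_r <- tr$R_b + tr$R_f
  tot_d <- tr$D_b + tr$D_f
  expect_lt(max(abs(tot_c - tot_c[1])) / tot_c[1], 1e-8)
  expect_lt(max(abs(tot_r - tot_r[1])) / tot_r[1], 1e-8)
  expect_lt(max(abs(tot_d - tot_d[1])) / tot_d[1], 1e-8)
})

test_that("trajectories started non-negative stay non-negative and receptors decay", {
  dp <- nondimensionalize(default_params())
  s0 <- wellmixed_state(c = 1, R_b = 0, R_f = 0.8, D_b = 0, D_f = 0.6)
  tr <- simulate_wellmixed(s0, dp, times = seq(0, 2, by = 0.05),
                           rtol = 1e-10, atol = 1e-14)
  expect_true(all(as.matrix(tr[, -1]) > -1e-12))
  expect_true(all(diff(tr$R_b + tr$R_f) <= 1e-10))
})

test_that("equilibrium occupancy matches its formula and an ODE oracle", {
  dp <- nondimensionalize(default_params())
  expect_equal(unname(wellmixed_equilibrium(0, dp)), c(0, 0))

  # closure term vanishes at beta = 1
  dp1 <- dp
  dp1$beta <- 1
  eq1 <- wellmixed_equilibrium(0.5, dp1)
  expect_equal(eq1[["rho_r"]], dp$k_a1 * 0.5 / (dp$k_d1 + dp$k_i1))

  # oracle: integrate d rho/dt = ka c (1+(beta-1) rho) - (kd+ki) rho at
  # frozen c = 1 to its long-time limit
  ode <- deSolve::ode(
    y = c(rho = 0), times = c(0, 10),
    func = function(t, y, q)
      list(q$k_a1 * 1 * (1 + (q$beta - 1) * y) - (q$k_d1 + q$k_i1) * y),
    parms = dp, rtol = 1e-12, atol = 1e-12)
  rho_inf <- ode[nrow(ode), "rho"]
  eq <- wellmixed_equilibrium(1, dp)
  expect_lt(abs(eq[["rho_r"]] - rho_inf) / rho_inf, 1e-6)

  # unbounded upregulation regime is signalled
  dph <- dp
  dph$beta <- 1.2
  dph$k_d1 <- 1e-4
  dph$k_i1 <- 0
  expect_error(wellmixed_equilibrium(1, dph), "denominator")
})

test_that("equilibrium agrees with a root of the frozen-ligand kinetics", {
  dp <- nondimensionalize(default_params())
  eq <- wellmixed_equilibrium(0.7, dp)
  f <- function(rho)
    dp$k_a1 * 0.7 * (1 + (dp$beta - 1) * rho) - (dp$k_d1 + dp$k_i1) * rho
  root <- uniroot(f, c(0, 1e3), tol = 1e-12)$root
  expect_equal(eq[["rho_r"]], root, tolerance = 1e-8)
})

test_that("receptor closure gives the free-receptor pool in both unit systems", {
  p <- default_params()
  # no binding: all receptors free
  expect_equal(closure_free_receptors(2, 0, p), p$Gamma_r * 2)
  # no cells: no receptors
  expect_equal(closure_free_receptors(0, 0.5, p), 0)
  # dimensionless free-receptor factor 1 + (beta-1) rho
  dp <- nondimensionalize(p)
  expect_equal(closure_free_receptors(1, 0.5, dp) / (dp$Gamma_r * 1),
               1 + (0.97 - 1) * 0.5)
  expect_equal(closure_free_receptors(1, 0.5, dp) / (dp$Gamma_r * 1), 0.985)
  # decoy analogue
  expect_equal(closure_free_receptors(1, 0, dp, receptor = "decoy"),
               dp$Gamma_d)
})

test_that("occupancy and bound-concentration views convert both ways", {
  expect_equal(occupancy_from_bound(6, n = 2, Gamma = 3), 1)
  expect_equal(bound_from_occupancy(1, n = 2, Gamma = 3), 6)
  x <- c(0.3, 1.7, 2.2)
  expect_equal(occupancy_from_bound(bound_from_occupancy(x, 2, 5), 2, 5), x)
})
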