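dp0 <- nondimensionalize(chamber_parameters())
g0 <- build_grid(dp0, h = 0.02)
nf0 <- length(g0$filter_idx)
xs0 <- (seq_len(nf0) - 1) * g0$h

test_that("the migrated count is the scaled trapezoid integral", {
  expect_equal(migrated_count(rep(1, nf0), 4e5, g0), 4e5)
  expect_equal(migrated_count(rep(0, nf0), 4e5, g0), 0)
  expect_equal(migrated_count(xs0, 2, g0), 1)   # trapezoid exact for x
})

test_that("the filter integral is additive over a node-aligned split", {
  set.seed(3)
  n <- runif(nf0)
  mid <- 26L  # x = 0.5
  left <- g0$h * (sum(n[1:mid]) - (n[1] + n[mid]) / 2)
  right <- g0$h * (sum(n[mid:nf0]) - (n[mid] + n[nf0]) / 2)
  expect_equal(left + right, decoychemo:::trapz_filter(n, g0$h))
})

test_that("penetration depth follows the threshold-supremum definition", {
  # everywhere above threshold: empty set, H = 1
  expect_equal(penetration_depth(rep(1, nf0), 4e5, g0), 1)
  # everywhere below: H = 0
  expect_equal(penetration_depth(rep(0, nf0), 4e5, g0), 0)
  # linear ramp crossing theta: interpolation locates the crossing exactly
  n0 <- 1 / 0.3   # theta = 0.3
  expect_equal(penetration_depth(xs0, n0, g0), 1 - 0.3)
  # step front at x = 0.6 with theta = 0.5: H -> 0.4 as the grid refines
  H_of_h <- sapply(c(0.02, 0.004), function(h) {
    g <- build_grid(dp0, h = h)
    m <- length(g$filter_idx)
    x <- (seq_len(m) - 1) * g$h
    penetration_depth(as.numeric(x >= 0.6), 2, g)
  })
  expect_lt(abs(H_of_h[1] - 0.4), 0.02)
  expect_lt(abs(H_of_h[2] - 0.4), 0.004)
  expect_true(abs(H_of_h[2] - 0.4) < abs(H_of_h[1] - 0.4))
})

test_that("raising n0 (lowering the threshold) never decreases H", {
  set.seed(11)
  for (k in 1:10) {
    n <- cumsum(runif(nf0, 0, 0.05))  # a monotone front-like profile
    hs <- sapply(c(1e2, 1e3, 1e5, 1e7), function(n0)
      penetration_depth(n, n0, g0))
    expect_true(all(diff(hs) >= -1e-12))
  }
})

test_that("percent change is definitional and guards its baseline", {
  expect_equal(percent_change(100, 185.19), 85.19)
  expect_equal(percent_change(200, 161.08), -19.46)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 1), "positive")
})

test_that("FL1-H rescaling is a fixed 1e9 factor", {
  expect_equal(fl1h_rescale(2.258e-8), 22.58)
  expect_equal(fl1h_rescale(0), 0)
  expect_equal(fl1h_rescale(1.8e-8), 18)
})

test_that("the unimodal argmax locator refines interior peaks", {
  xs <- 0:6
  ys <- -(xs - 3)^2
  expect_equal(find_unimodal_argmax(xs, ys), 3)
  # monotone responses have no interior maximum
  expect_error(find_unimodal_argmax(xs, xs), "no interior maximum")
  expect_error(find_unimodal_argmax(xs, rev(xs)), "no interior maximum")
  # golden-section refinement against a known smooth peak
  f <- function(x) -(x - 2.7)^2
  xstar <- find_unimodal_argmax(xs, f(xs), f = f, tol = 1e-8)
  expect_equal(xstar, 2.7, tolerance = 1e-6)
})

test_that("a one-point ligand sweep reproduces a direct simulation", {
  p <- default_params()
  tab <- sweep_c0(p, 6e-8, h = fast_ctl$h, dt = fast_ctl$dt, t_max = 0.5)
  direct <- fast_run(p, t_max = 0.5)
  expect_equal(tab$N_f, final_nf(direct))
  expect_equal(tab$H, final_h(direct))
  expect_equal(tab$c0_fl1h, 60)
  expect_equal(tab$status, "ok")
})

test_that("c0 enters the dimensionless system only through k_a and Gamma", {
  p <- default_params()
  dp1 <- nondimensionalize(p)
  p2 <- p
  p2$c0 <- 2 * p$c0
  dp2 <- nondimensionalize(p2)
  expect_equal(dp2$k_a1, 2 * dp1$k_a1)
  expect_equal(dp2$k_a2, 2 * dp1$k_a2)
  expect_equal(dp2$Gamma_r, dp1$Gamma_r / 2)
  expect_equal(dp2$Gamma_d, dp1$Gamma_d / 2)
  same <- setdiff(names(unclass(dp1)),
                  c("k_a1", "k_a2", "Gamma_r", "Gamma_d"))
  for (nm in same) expect_equal(dp2[[nm]], dp1[[nm]], info = nm)
})

test_that("sweep rows fail in isolation", {
  p <- default_params()
  # the second concentration makes the explicit reaction update unstable:
  # that row is marked, the first still completes
  tab <- sweep_c0(p, c(6e-8, 1e-4), h = fast_ctl$h, dt = fast_ctl$dt,
                  t_max = 0.2)
  expect_equal(tab$status[1], "ok")
  expect_false(tab$status[2] == "ok")
  expect_true(is.na(tab$N_f[2]))
  expect_false(is.na(tab$N_f[1]))
})
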