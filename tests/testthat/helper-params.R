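# shared fixtures: all synthetic inputs are built in code

default_params <- function(...) chamber_parameters(...)

# coarse-but-faithful controls for tests that probe structure, not accuracy
fast_ctl <- list(h = 0.04, dt = 2e-4)

fast_run <- function(params, ...) {
  simulate_chamber(params, h = fast_ctl$h, dt = fast_ctl$dt,
                   snapshot_times = numeric(0), ...)
}

final_nf <- function(sim) sim$series$N_f[nrow(sim$series)]
final_h <- function(sim) sim$series$H[nrow(sim$series)]

# dimensionless set with all binding/unbinding/internalization switched off
kinetics_off <- function(dp) {
  for (nm in c("k_a1", "k_a2", "k_d1", "k_d2", "k_i1", "k_i2"))
    dp[[nm]] <- 0
  dp
}

# deterministic pseudo-random admissible state on a given grid
random_state <- function(grid, seed = 1) {
  set.seed(seed)
  nf <- length(grid$filter_idx)
  st <- initial_state(grid, NULL)
  st$n <- runif(nf)
  st$c <- runif(grid$n_total)
  st$rho_r <- 30 * runif(nf)
  st$rho_d <- 30 * runif(nf)
  st
}

grid_info <- function(grid) {
  list(h = grid$h, n_total = grid$n_total, i0 = grid$i0, i1 = grid$i1)
}

par_vec_of <- function(dp) {
  c(D_n = dp$D_n, D_c = dp$D_c, chi = dp$chi, mu = dp$mu,
    k_a1 = dp$k_a1, k_a2 = dp$k_a2, k_d1 = dp$k_d1, k_d2 = dp$k_d2,
    k_i1 = dp$k_i1, k_i2 = dp$k_i2, Gamma_r = dp$Gamma_r,
    Gamma_d = dp$Gamma_d, beta = dp$beta, delta = dp$delta, L = dp$L)
}
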