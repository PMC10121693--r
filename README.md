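# decoychemo

Deterministic simulation of glioma-cell migration through a Boyden-chamber
filter, driven by CD95/CD95L receptor–ligand kinetics in the presence of
the decoy receptor DcR3.

Decoy receptors of the TNF-receptor superfamily bind ligand without
transducing a migratory signal. DcR3 sequesters CD95L and thereby blunts
the chemotactic response that bound CD95 would otherwise drive. This
package implements a four-field continuum model of that competition for
people who want to explore, in silico, how ligand dose, receptor
upregulation, and decoy expression shape transwell-migration readouts:
the number of cells that enter the filter and the depth their wavefront
reaches.

## Model

The chamber is one-dimensional: a lower well `[-L_l, 0]` loaded with
ligand, the filter `[0, 1]`, and an upper well `[1, 1 + L_u]` loaded with
cells (lengths in filter-thickness units). On the filter the dimensionless
fields are the cell density `n(x,t)`, the ligand `c(x,t)` (defined on the
whole chamber), and the per-cell bound receptor occupancies `rho_r`
(CD95, chemo-attractant) and `rho_d` (DcR3, chemo-repellent):

    K_n   = -D_n n_x + chi n (rho_r)_x - mu n (rho_d)_x
    n_t   = -dK_n/dx
    c_t   = D_c c_xx + kd1 Gr n rho_r - ka1 c n Gr (1 + (beta-1) rho_r)
                     + kd2 Gd n rho_d - ka2 c n Gd (1 + (delta-1) rho_d)
    rho_r,t = -(K_n/n) (rho_r)_x + ka1 c (1 + (beta-1) rho_r) - (kd1+ki1) rho_r
    rho_d,t = -(K_n/n) (rho_d)_x + ka2 c (1 + (delta-1) rho_d) - (kd2+ki2) rho_d

with pure ligand diffusion `c_t = D_c c_xx` in the wells, reservoir-
exchange boundary rows `n_t = -K_n/L` at `x = 0` and `+K_n/L` at `x = 1`
(`L` the cell diameter), zero-gradient occupancies at the filter faces,
and no-flux ligand conditions at the chamber ends. The upregulation
closure `R_b + R_f = Gamma_r (n + beta R_b)` (decoy analogue with
`Gamma_d`, `delta`) eliminates the free-receptor fields; `beta Gamma_r`
and `delta Gamma_d` must stay below 1 for the receptor pool to remain
bounded.

Observables:

* `N_f = n0 * integral of n over the filter` — migrated cell count;
* `H = 1 - sup{x : n(x) < 1/n0}` — wavefront penetration depth;
* `S_j = p_j * integral of dn/dp_j / integral of n` — normalized forward
  sensitivity of `N_f` to each of (`chi`, `mu`, `beta`, `delta`, `k_a2`,
  `k_d2`, `k_i2`, `Gamma_d`), co-integrated as tangent fields with the
  primal PDE and cross-checked against central finite differences.

Numerics: central differences on a uniform grid (`h = 0.02` by default),
forward Euler at `dt = 1e-6` or an IMEX scheme (Crank–Nicolson ligand
diffusion, explicit transport/kinetics) at `dt = 1e-4`; the two steppers
agree on `N_f(t = 5)` to better than 0.1%. A first-order upwind fallback
is available for fine grids where central advection of the steep cell
front loses positivity.

## Worked example

```r
library(decoychemo)

p <- chamber_parameters()          # reference assay configuration
validate_parameters(p)             # character(0): all invariants hold
sim <- simulate_chamber(p)         # IMEX, h = 0.02, dt = 1e-4, t = 5 h
sim
#> chamber simulation (full system, imex stepper, h = 0.02, dt = 1e-04)
#>   t = 5 h: N_f = 17374.2 cells, H = 0.7165
#>   3 snapshots, 101 series points, 9431 clipped values
```

About 17 400 of the 4e5 cells/cm^3 loaded in the upper well are in the
filter after five hours, and the wavefront (the deepest point whose
density exceeds one cell/cm^3) has crossed 72% of the filter. Removing
the decoy receptors or raising the CD95 upregulation factor `beta`
increases `N_f`; raising the DcR3 factor `delta` decreases it:

```r
tail(sensitivity_table(p, method = "forward"), n = -4)[, c("parameter", "S")]
#>   parameter             S
#> 5      k_a2 -2.307524e-05
#> 6      k_d2 -2.365277e-06
#> 7      k_i2 -6.532387e-07
#> 8   Gamma_d -6.511354e-10
forward_sensitivity(p, "chi")
#> S_chi = 0.00779789  (forward, tau = 5, baseline 0.15936)
```

The migrated count responds unimodally to the ligand dose: with
`n0 = 5e3` cells/cm^3 the count-versus-concentration curve peaks at

```r
thr <- find_c0_threshold(chamber_parameters(n0 = 5e3),
                         c0_range = c(5e-9, 5e-8), observable = "N_f")
fl1h_rescale(thr$c_T)
#> [1] 21.26289
```

on the FL1-H axis (ligand concentration times 1e9) used for comparison
with flow-cytometry count tables; beyond that dose, receptor saturation
flattens the occupancy gradient and migration declines.
`synthesize_counts_curve()` generates unimodal synthetic count tables for
exercising the comparison path (`read_counts_curve()`,
`compare_model_to_counts()`) when no experimental table is at hand.

A command-line front end wraps the same functions:

```sh
Rscript exec/decoychemo simulate --config inst/extdata/default_assay.cfg --out out/
Rscript exec/decoychemo sensitivity --config inst/extdata/default_assay.cfg --out out/
Rscript exec/decoychemo params-echo   # dimensionless parameter set as JSON
```

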