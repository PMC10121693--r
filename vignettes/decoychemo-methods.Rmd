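---
title: "decoychemo: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{decoychemo: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters and what they mean, the discretization and
every numerical safeguard, and the choices made where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The biological setting

Transwell (Boyden-chamber) assays quantify chemotaxis: cells loaded in an
upper well migrate into a porous filter toward ligand placed in a lower
well, and after a fixed incubation one counts cells in the filter and
measures how deep their wavefront reached. For glioma cells the relevant
signaling pair is the death receptor CD95 and its ligand CD95L: bound
CD95 promotes directed migration. Malignant cells additionally express
the decoy receptor DcR3, a soluble TNF-receptor-superfamily member that
binds CD95L without signaling; occupancy of the decoy channel is treated
here as chemo-repellent, so the two receptor classes pull the cells in
opposite directions along their respective occupancy gradients.

## Governing equations

All computations are done in dimensionless form. Lengths are scaled by
the filter thickness `L_f`, time by `T_scale` (3600 s, so dimensionless
time is in hours), cell density by the upper-well loading `n0`, ligand by
the lower-well loading `c0`, and the per-cell bound occupancies by the
receptor loads `Gamma_r` and `Gamma_d`. The chamber is the interval
`[-L_l/L_f, 1 + L_u/L_f]`; the filter is `[0, 1]`.

Four fields evolve. The cell flux combines random motility, attraction up
the bound-CD95 gradient, and repulsion up the bound-DcR3 gradient,

    K_n = -D_n n_x + chi n (rho_r)_x - mu n (rho_d)_x,

and drives `n_t = -dK_n/dx` on the filter interior. The ligand diffuses
through the whole chamber and exchanges mass with the receptor pools on
the filter; the occupancies advect with the cells at velocity `K_n / n`
and follow mass-action loading with upregulated receptor totals
(`R_b + R_f = Gamma_r (n + beta R_b)`, decoy analogue with `delta`),
which eliminates the free-receptor fields and yields the loading factor
`1 + (beta - 1) rho_r`. The dimensionless upregulation factors
`beta * Gamma_r` and `delta * Gamma_d` must stay below one; at or above
one the per-cell receptor number grows without bound, and
`validate_parameters()` flags such configurations.

Assumptions inherited from the model class: radial variation in the
chamber is neglected (one spatial dimension); the kinetics are
deterministic mass action; internalized receptor-ligand complexes are
destroyed, not recycled, so ligand mass decays at the internalization
rates; cells neither divide nor die on the assay timescale; and the upper
well is represented only through the boundary exchange row, not as a
depleting reservoir state.

### Initial and boundary conditions

At `t = 0` the ligand fills the lower well (`c = 1` for `x <= 0`,
including the interface node) and is absent elsewhere; the occupancies
are zero; and the cell field is zero on the filter except `n = 1` at the
`x = 1` node. This is the literal point-loading reading of the assay: the
cells sit at the filter's upper face, and the boundary rows
`n_t = -K_n/L` at `x = 0` and `+K_n/L` at `x = 1` (`L` the cell diameter
in filter units) exchange cells between the faces and the adjoining
compartments. The orientation — ligand below, cells above, migration in
the direction of decreasing `x` — is the only one under which the initial
conditions, the boundary rows, and the observed front direction are
mutually consistent. Occupancies carry zero-gradient ghost values at both
filter faces; the ligand has no-flux mirror ghosts at the chamber ends
and lives on one continuous grid, so flux continuity at the
filter-well interfaces is automatic.

One consequence deserves emphasis: the initial cell mass on the filter is
`h/2` under the trapezoid rule — it depends on the grid. Integral
observables dominated by the boundary influx (such as `N_f(t=5)`) are
nearly grid-independent (coarsening `h` from 0.02 to 0.04 moves `N_f` by
about 0.1%), but quantities that weigh the transient transport of that
point mass — notably the parameter sensitivities — inherit a real
`h`-dependence. The test suite documents this rather than hiding it.

## Parameters

`chamber_parameters()` holds the dimensional set; defaults are the
package's reference assay. Motility and transport: `D_n = 1.3e-10`
cm²/s (cell random motility), `D_c = 7.3e-6` cm²/s (ligand diffusivity),
`chi = 2e12` and `mu = 1e10` cm²/(s·mol) (attractant/repellent
coefficients). Kinetics per receptor class: association `k_a1 = 1.67e7`,
`k_a2 = 8.33e7` cm³/(s·ligand-unit); dissociation `k_d1 = 0.0058`,
`k_d2 = 0.0029` /s; internalization `k_i1 = 0.004`, `k_i2 = 8e-4` /s.
Receptor loads `Gamma_r = 4.98e-21`, `Gamma_d = 3.984e-21` mol/cell, with
upregulation rates defaulting to dimensionless factors `beta~ = 0.97` and
`delta~ = 0.952` (`with_upregulation()` sets the factors directly).
Geometry: cell diameter `9.2e-4` cm; well heights `L_u = 0.0375`,
`L_f = 0.015`, `L_l = 0.03125` cm. Loadings: `n0 = 4e5` cells/cm³,
`c0 = 6e-8` ligand-unit/cm³.

The ligand unit is deliberately opaque. Only the products
`k_a * T_scale * c0` and the ratios `Gamma * n0 / c0` enter the
dimensionless system, so no molar-mass conversion is ever performed; the
package does not attempt to reconcile mass-based and molar ligand units,
it simply requires `c0`, `k_a` and `Gamma` to be expressed consistently.
`params_echo()` prints the derived dimensionless set — the
non-dimensionalization happens exactly once per run, and that JSON record
is its canonical log.

## Discretization and stepping

The chamber is discretized uniformly. The requested spacing is snapped to
`1/round(1/h)` so that both filter faces fall exactly on nodes, and the
well lengths to whole multiples of the spacing; all snapping is recorded
on the grid object. The default `h = 0.02` resolves the filter with 51
nodes (280 nodes chamber-wide).

Spatial derivatives are central differences; the flux gradients use
one-sided second-order stencils at the filter faces, so the scheme is
second order throughout (verified against an exact decaying cosine mode
in the tests). Two steppers are provided:

* **Forward Euler**, `dt = 1e-6` h. The stiff ligand-diffusion term
  imposes `dt <= h^2 / (2 D_c~)`; the stepper refuses steps beyond the
  bound unless explicitly overridden, and
  `diffusion_stability_ratio()` reports the margin.
* **IMEX**, `dt = 1e-4` h: Crank–Nicolson for ligand diffusion
  (tridiagonal solves, unconditionally stable, second order), explicit
  everything else. Because the initial ligand profile is a step, plain
  Crank–Nicolson rings at the grid Fourier number this step size implies;
  the first four steps therefore use backward Euler (Rannacher
  smoothing), which damps the startup modes without affecting the
  asymptotic order. The two steppers agree on `N_f(t = 5)` to better
  than 0.1%, so the IMEX path is used for parameter sweeps and
  sensitivity tables at roughly 1/25th the cost.

Safeguards: values in `[-1e-10, 0)` produced by the explicit updates are
clipped to zero and counted (the count is part of the run metadata); any
excursion below `-1e-10` aborts the run naming the field. The occupancy
advection velocity `K_n / n` is evaluated only where `n >= 1e-12` —
occupancy is a per-cell quantity, undefined without cells — and the
advection term is dropped at nodes below that floor, leaving the
occupancy dynamics purely kinetic until cells arrive.

The default central advection keeps the cell field non-negative at the
reference resolution, but at finer spacings (`h <= 0.01`) the cell
Péclet number at the steep front exceeds the monotonicity limit and the
scheme oscillates into the abort. For such runs
`advection = "upwind"` switches the cell and occupancy advection to a
first-order donor-cell discretization; it smears the front (at `t = 1`
the two schemes differ by some tens of percent in `N_f`, converging as
the grid refines) but is positivity-robust. The sensitivity tangent is
implemented for the central scheme only, and the driver enforces that.

A reduced three-field system (no decoy class) is implemented as an
independent code path, not as the full solver with zeroed parameters; the
tests verify the two agree node-for-node (at machine precision) when all
decoy parameters vanish, which is the discrete counterpart of the
statement that a zero initial decoy occupancy admits only the trivial
decoy solution.

## Observables and sweep protocol

`migrated_count()` integrates `n` over the filter by the trapezoid rule
(consistent with the second-order stencil) and scales by `n0`.
`penetration_depth()` implements `H = 1 - sup{x : n(x) < 1/n0}` with the
supremum located on the grid and refined by linear interpolation between
the bracketing nodes — interpolation removes the `h`-sized quantization
that would otherwise dominate threshold sweeps. Conventions: an empty
sub-threshold set gives `H = 1`; an entirely sub-threshold profile gives
`H = 0`.

`sweep_c0()` re-derives the dimensionless parameter set for every ligand
dose — `c0` enters through `k_a * T_scale * c0` and `Gamma * n0 / c0`,
which is the only reading under which the dose affects the dimensionless
dynamics at all. `find_c0_threshold()` locates the over-stimulation
threshold (the dose beyond which more ligand reduces migration) by a
coarse sweep plus golden-section refinement that re-simulates at every
probe (no surrogate fitting; bracket tolerance `1e-10` on `c0`). The
mechanism behind the interior maximum is receptor saturation: occupancy
equilibrates near `k_a~ c / (k_d~ + k_i~ + k_a~ c (1 - beta~))`, and once
`k_a~ c (1 - beta~)` dominates the denominator the occupancy gradient —
hence the chemotactic drive — flattens.

Default sweep ranges are package choices: the penetration-depth threshold
study scans `c0` in `[5e-9, 4e-7]`, wide enough to bracket the model's
own turning point on both sides; the count-curve study at `n0 = 5e3`
scans `[5e-9, 5e-8]`, i.e. 5–50 on the FL1-H axis (`c0 * 1e9`), matching
the span over which cytometry count tables are reported.

## Forward sensitivity analysis

For each parameter `p_j` among (`chi`, `mu`, `beta`, `delta`, `k_a2`,
`k_d2`, `k_i2`, `Gamma_d`) the tangent fields `s = d(state)/dp_j` are
co-integrated with the primal system. The tangent right-hand side is the
full total derivative — the explicit `dF/dp_j` term plus the
Jacobian-vector products through the state, its gradient, and its
Laplacian — on the same grid and stepper, with the linearized
reservoir-exchange rows at the filter faces and tangent entries zeroed
wherever the primal clip fires (the derivative of the clipped map).
Differentiation is with respect to the dimensionless parameter at its
baseline; the reported index

    S_j = p_j * integral(s_n) / integral(n)   at tau = 5

is an elasticity, invariant to the units in which `p_j` is expressed.
`fd_sensitivity()` provides the independent oracle: central finite
differences of two full primal solves at `p_j (1 ± r)`. The suite checks
agreement within 5% at the reference resolution and the expected
quadratic shrinkage of the finite-difference truncation gap. A
multiplicative perturbation of a structurally zero parameter is a no-op,
so its index is reported as exactly zero.

Two practical notes. First, perturbing `beta~` upward near 1 can leave
the admissible region (unbounded upregulation); the finite-difference
step must respect that, which is why the truncation study perturbs `chi`.
Second, as discussed above the indices inherit the grid sensitivity of
the point-loaded initial condition: they are stable under `dt` refinement
and across steppers (sub-2% movement) but not under `h` refinement, and
the suite records that honestly rather than asserting a stability the
construction does not possess.

## The synthetic counts fixture

`synthesize_counts_curve()` emulates the shape of a migrated-count versus
ligand-concentration table from a flow-cytometry experiment: a skewed
unimodal bump `peak_count * (f/p)^k * exp(k (1 - f/p))` (default shape
`k = 3`, peaking at FL1-H 18) plus zero-truncated Gaussian noise from an
explicitly seeded generator that leaves the session RNG untouched. It
reproduces the qualitative features the comparison path needs — a rising
limb, a single interior peak, a falling limb, non-negative counts — and
nothing else: no cytometry gating artifacts, no heteroscedastic counting
noise, no replicate structure. Passing tests against this fixture
therefore validate the I/O and comparison machinery
(`read_counts_curve()`, `compare_model_to_counts()`), not agreement with
any real cell line. The comparison report is deliberately fitting-free:
each curve's argmax, a min–max normalized RMSE on the overlapping FL1-H
range (model interpolated onto the data abscissae), and the post-peak
slope signs. Min–max normalization makes the score invariant to affine
rescalings of the counts, which is intended — model cell counts and
cytometry counts live on unrelated scales, so only shape is compared.

## Problem sizes used by the tests

The suite runs the reference configuration at `h = 0.02` with IMEX
`dt = 1e-4` for end-to-end checks (each five-hour run takes well under a
second), forward Euler at `dt = 1e-6` for the cross-scheme and
conservation checks, and a coarse `h = 0.04`, `dt = 2e-4` setting for
structural tests where quantitative accuracy is not the point.
Convergence orders are measured on a small three-compartment chamber with
a smooth shifted-cosine ligand mode, where the semi-discrete decay is
known in closed form.

## Known limitations

* One spatial dimension; no radial geometry, no cell sedimentation, no
  alternative chamber designs.
* The upper well is not a depleting reservoir; cells enter only through
  the face exchange row, so very long runs overstate the supply.
* The point-loaded initial cell condition ties a small amount of initial
  mass (`h/2`) to the grid, with the sensitivity-index consequences
  described above.
* The central advection scheme loses positivity at fine grids; the
  upwind fallback trades that for first-order front smearing.
* Ligand destruction by internalization is permanent; systems with
  substantial receptor recycling are outside the model.
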