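#' Migrated-cell count in the filter
#'
#' `N_f = n0 * integral of n over the filter`, evaluated by the trapezoid
#' rule on the uniform grid (the quadrature order matches the
#' second-order spatial stencil).
#'
#' @param n dimensionless cell density on the filter nodes (>= 0)
#' @param n0 initial upper-well cell density (cells/cm^3)
#' @param grid a [build_grid()] object (supplies the spacing)
#' @return migrated cell count (cells)
#' @export
migrated_count <- function(n, n0, grid) {
  stopifnot(all(n >= 0), n0 > 0)
  n0 * trapz_filter(n, grid$h)
}

#' Wavefront penetration depth
#'
#' `H = 1 - sup{ x : n(x) < 1/n0 }`: one minus the deepest position whose
#' cell density is still below one cell per cm^3 (dimensionless threshold
#' `1/n0`).  The supremum is located on the grid and refined by linear
#' interpolation between the bracketing nodes, which removes the grid-size
#' quantization from threshold sweeps.  Conventions: if no node is below
#' threshold the supremum over the empty set is taken as 0, so `H = 1`;
#' if every node is below threshold the supremum is 1 and `H = 0`.
#'
#' @inheritParams migrated_count
#' @return penetration depth in filter-thickness units, in `[0, 1]`
#' @export
penetration_depth <- function(n, n0, grid) {
  stopifnot(all(n >= 0), n0 > 0)
  theta <- 1 / n0
  m <- length(n)
  below <- which(n < theta)
  if (length(below) == 0) return(1)
  i <- max(below)
  if (i == m) return(0)
  x_i <- (i - 1) * grid$h
  sup <- x_i + grid$h * (theta - n[i]) / (n[i + 1] - n[i])
  1 - sup
}

#' Percent change of a scalar observable
#'
#' `100 * (variant - reference) / reference`; positive when the variant
#' exceeds the reference.
#'
#' @param reference baseline value (> 0)
#' @param variant value to compare
#' @return percent change
#' @export
percent_change <- function(reference, variant) {
  if (reference <= 0) stop("reference must be strictly positive")
  100 * (variant - reference) / reference
}

#' Sweep the initial ligand concentration
#'
#' Runs one full simulation per `c0` value, all other dimensional inputs
#' held fixed, and tabulates the migration observables at the final time.
#' Each row re-derives the dimensionless parameter set, so `c0` enters the
#' dynamics through the scaled association rates (`k_a * T * c0`) and
#' receptor loads (`Gamma * n0 / c0`).  Row failures are isolated: the
#' remaining rows still run and failed rows are marked in `status`.
#'
#' @param params a [chamber_parameters()] object; its `c0` is replaced per
#'   row
#' @param c0_values ligand concentrations to sweep (ligand-unit/cm^3, all
#'   > 0), reported in input order
#' @param ... simulation controls forwarded to [simulate_chamber()]
#'   (`h`, `dt`, `t_max`, `stepper`, ...)
#' @return data.frame with columns `c0`, `c0_fl1h`, `N_f`, `H`, `status`
#' @export
sweep_c0 <- function(params, c0_values, ...) {
  stopifnot(inherits(params, "chamber_parameters"), all(c0_values > 0))
  rows <- lapply(c0_values, function(v) {
    p <- params
    p$c0 <- v
    tryCatch({
      sim <- simulate_chamber(p, snapshot_times = numeric(0), ...)
      last <- sim$series[nrow(sim$series), ]
      data.frame(c0 = v, c0_fl1h = fl1h_rescale(v),
                 N_f = last$N_f, H = last$H, status = "ok")
    }, error = function(e) {
      data.frame(c0 = v, c0_fl1h = fl1h_rescale(v), N_f = NA_real_,
                 H = NA_real_, status = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}

#' Locate the interior maximum of a unimodal response
#'
#' Finds the argmax on the coarse grid and, when an evaluation function
#' is supplied, refines it by golden-section search between the
#' bracketing neighbors until the bracket is smaller than `tol` (each
#' refinement evaluation is a full re-simulation in the sweeping use
#' case; no surrogate is fitted).  Without an evaluation function the
#' vertex of the parabola through the three bracketing points is
#' returned.
#'
#' @param xs strictly increasing abscissae (length >= 3)
#' @param ys responses, unimodal up to noise
#' @param f optional function `f(x)` returning the response at an
#'   arbitrary `x`, used for golden-section refinement
#' @param tol bracket tolerance for the refinement (same units as `xs`)
#' @return the refined argmax `x*`
#' @export
find_unimodal_argmax <- function(xs, ys, f = NULL,
                                 tol = diff(range(xs)) * 1e-3) {
  stopifnot(length(xs) >= 3, length(xs) == length(ys),
            all(diff(xs) > 0))
  k <- which.max(ys)
  if (k == 1L || k == length(ys))
    stop("no interior maximum: the response is monotone over the sweep range")
  a <- xs[k - 1]; b <- xs[k + 1]
  if (is.null(f)) {
    # parabola through the three bracketing points
    x1 <- xs[k - 1]; x2 <- xs[k]; x3 <- xs[k + 1]
    y1 <- ys[k - 1]; y2 <- ys[k]; y3 <- ys[k + 1]
    den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
    if (den == 0) return(x2)
    xv <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / den
    return(min(max(xv, a), b))
  }
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Rescale a ligand concentration to the FL1-H axis
#'
#' The flow-cytometry comparison uses the FL1-H fluorescence channel as a
#' relative ligand-concentration axis; the model maps `c0` onto it with a
#' fixed `1e9` scale factor.
#'
#' @param c0 ligand concentration (>= 0)
#' @return FL1-H value (`c0 * 1e9`)
#' @export
fl1h_rescale <- function(c0) {
  stopifnot(all(c0 >= 0))
  c0 * 1e9
}

#' Over-stimulation threshold of a migration observable
#'
#' Sweeps `c0` on a coarse grid, then refines the interior maximum of the
#' chosen observable (`H` or `N_f` at the final time) by golden-section
#' re-simulation.  This is the ligand concentration beyond which more
#' ligand reduces migration.
#'
#' @param params a [chamber_parameters()] object
#' @param c0_range range of `c0` to sweep
#' @param n_coarse number of coarse sweep points
#' @param observable `"H"` or `"N_f"`
#' @param tol bracket tolerance on `c0` for the refinement
#' @param ... simulation controls forwarded to [simulate_chamber()]
#' @return list with the refined threshold `c_T`, the coarse sweep table,
#'   and the observable used
#' @export
find_c0_threshold <- function(params, c0_range = c(5e-9, 6e-8),
                              n_coarse = 8, observable = c("H", "N_f"),
                              tol = 1e-10, ...) {
  observable <- match.arg(observable)
  c0s <- seq(c0_range[1], c0_range[2], length.out = n_coarse)
  tab <- sweep_c0(params, c0s, ...)
  if (any(tab$status != "ok"))
    stop("coarse sweep failed for c0 = ",
         paste(tab$c0[tab$status != "ok"], collapse = ", "))
  ys <- tab[[observable]]
  f <- function(c0) {
    p <- params
    p$c0 <- c0
    sim <- simulate_chamber(p, snapshot_times = numeric(0), ...)
    sim$series[[observable]][nrow(sim$series)]
  }
  c_T <- find_unimodal_argmax(tab$c0, ys, f = f, tol = tol)
  list(c_T = c_T, sweep = tab, observable = observable)
}
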