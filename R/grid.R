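#' Discretize the Boyden chamber on a uniform 1-D grid
#'
#' Builds the node set spanning the lower well `[-L_l, 0]`, the filter
#' `[0, 1]` and the upper well `[1, 1 + L_u]` (all lengths in
#' filter-thickness units).  The spacing is snapped to `1 / round(1 / h)`
#' so that the interfaces `x = 0` and `x = 1` fall exactly on nodes, and
#' the well lengths are snapped to whole multiples of the spacing; any
#' snapping is recorded in the `notes` field.
#'
#' @param dp a `chamber_dimensionless` parameter set (supplies `L_l`,
#'   `L_u`)
#' @param h requested node spacing in filter-thickness units (0 < h <= 0.5)
#' @return an object of class `chamber_grid`: list with spacing `h`, node
#'   coordinates `x`, total node count `n_total`, interface indices `i0`
#'   (x = 0) and `i1` (x = 1), `filter_idx`, the snapped well lengths, and
#'   `notes` describing adjustments
#' @export
build_grid <- function(dp, h = 0.02) {
  stopifnot(inherits(dp, "chamber_dimensionless"), h > 0, h <= 0.5)
  notes <- character(0)
  nf <- round(1 / h)
  h_used <- 1 / nf
  if (abs(h_used - h) > 1e-12 * h) {
    notes <- c(notes, sprintf(
      "spacing snapped from %g to 1/%d = %g so the filter ends on nodes",
      h, nf, h_used))
  }
  if (nf + 1L < 11L)
    notes <- c(notes, sprintf(
      "filter resolved by only %d nodes; at least 11 are recommended", nf + 1L))
  nl <- max(1L, round(dp$L_l / h_used))
  nu <- max(1L, round(dp$L_u / h_used))
  Ll_used <- nl * h_used
  Lu_used <- nu * h_used
  if (abs(Ll_used - dp$L_l) > 1e-12)
    notes <- c(notes, sprintf("lower-well length snapped from %g to %g",
                              dp$L_l, Ll_used))
  if (abs(Lu_used - dp$L_u) > 1e-12)
    notes <- c(notes, sprintf("upper-well length snapped from %g to %g",
                              dp$L_u, Lu_used))
  x <- ((-nl):(nf + nu)) * h_used
  g <- list(h = h_used, x = x, n_total = length(x),
            i0 = nl + 1L, i1 = nl + nf + 1L,
            filter_idx = (nl + 1L):(nl + nf + 1L),
            L_l = Ll_used, L_u = Lu_used, notes = notes)
  class(g) <- "chamber_grid"
  g
}

#' @export
print.chamber_grid <- function(x, ...) {
  cat(sprintf("chamber grid: h = %g, %d nodes on [%g, %g], filter nodes %d..%d\n",
              x$h, x$n_total, x$x[1], x$x[x$n_total], x$i0, x$i1))
  for (w in x$notes) cat("  note:", w, "\n")
  invisible(x)
}

# trapezoid integral of a field sampled on the uniform filter nodes
trapz_filter <- function(f, h) {
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

# trapezoid integral over the whole chamber grid
trapz_chamber <- function(f, h) {
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}
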