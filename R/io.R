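#' Read a plain-text parameter configuration
#'
#' Parses a `key: value` file (one entry per line, `#` comments and blank
#' lines ignored).  Keys are the dimensional parameter names of
#' [chamber_parameters()] plus the stepping controls `h`, `dt`, `t_max`,
#' `stepper`, and `record_dt`.  Unknown keys are an error, so typos never
#' silently fall back to defaults.
#'
#' @param path file to read
#' @return list with elements `params` (a `chamber_parameters` object)
#'   and `controls` (named list of stepping controls present in the file)
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  par_keys <- names(formals(chamber_parameters))
  ctl_keys <- c("h", "dt", "t_max", "stepper", "record_dt")
  unknown <- setdiff(keys, c(par_keys, ctl_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num <- function(k, v) {
    if (k == "stepper") return(v)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric value for key '", k, "': ", v)
    x
  }
  entries <- stats::setNames(Map(num, keys, vals), keys)
  params <- do.call(chamber_parameters, entries[intersect(keys, par_keys)])
  list(params = params, controls = entries[intersect(keys, ctl_keys)])
}

#' Write a parameter configuration
#'
#' @param params a [chamber_parameters()] object
#' @param path file to write
#' @param controls optional named list of stepping controls to include
#' @return `path`, invisibly
#' @export
write_config <- function(params, path, controls = list()) {
  stopifnot(inherits(params, "chamber_parameters"))
  ent <- c(unclass(params), controls)
  writeLines(sprintf("%s: %s", names(ent),
                     vapply(ent, format, "", digits = 17)), path)
  invisible(path)
}

#' Dimensionless parameter set as JSON
#'
#' Serializes the derived tilde parameters (plus the scales used) for
#' logging and for the `params-echo` command-line subcommand; the
#' dimensionless set is derived exactly once per run and this is its
#' canonical record.
#'
#' @param params a [chamber_parameters()] object
#' @return a JSON string (class `json`)
#' @export
params_echo <- function(params) {
  dp <- nondimensionalize(params)
  jsonlite::toJSON(c(unclass(dp), list(scales = attr(dp, "scales"))),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a migrated-count-vs-concentration curve
#'
#' Reads a two-column CSV (header required) of relative ligand
#' concentration on the FL1-H axis and migrated cell count, as
#' re-exported from a flow-cytometry supplement.  Rows are sorted by
#' FL1-H (with a warning if the input was unsorted); duplicate FL1-H
#' values, non-numeric entries and negative counts are errors.
#'
#' @param path CSV file; lines starting with `#` are ignored
#' @param source tag recorded on the curve: `"experimental"`,
#'   `"synthetic"` or `"model"`
#' @return a `counts_curve`: data.frame with columns `fl1h`, `count` and
#'   attribute `source`
#' @export
read_counts_curve <- function(path, source = "experimental") {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("expected two columns (fl1h, count)")
  df <- df[, 1:2]
  names(df) <- c("fl1h", "count")
  if (!is.numeric(df$fl1h) || !is.numeric(df$count))
    stop("non-numeric rows in counts curve")
  if (anyNA(df)) stop("missing values in counts curve")
  counts_curve(df$fl1h, df$count, source = source)
}

#' Construct a counts curve
#'
#' @param fl1h relative ligand concentrations (FL1-H units)
#' @param count migrated cell counts (>= 0)
#' @param source provenance tag
#' @return a `counts_curve` data.frame, sorted by `fl1h`
#' @export
counts_curve <- function(fl1h, count,
                         source = c("model", "synthetic", "experimental")) {
  source <- match.arg(source)
  stopifnot(length(fl1h) == length(count))
  if (anyDuplicated(fl1h)) stop("duplicate fl1h values")
  if (any(count < 0)) stop("negative counts")
  if (is.unsorted(fl1h)) {
    warning("counts curve was not sorted by fl1h; sorting")
    o <- order(fl1h)
    fl1h <- fl1h[o]; count <- count[o]
  }
  structure(data.frame(fl1h = fl1h, count = count),
            source = source, class = c("counts_curve", "data.frame"))
}

#' Write a counts curve as CSV
#'
#' A provenance comment line (source tag and generation arguments, when
#' present) is embedded before the header so the file is self-describing;
#' [read_counts_curve()] skips it.
#'
#' @param curve a `counts_curve`
#' @param path file to write
#' @return `path`, invisibly
#' @export
write_counts_curve <- function(curve, path) {
  stopifnot(inherits(curve, "counts_curve"))
  prov <- attr(curve, "provenance")
  hdr <- sprintf("# source: %s%s", attr(curve, "source"),
                 if (is.null(prov)) "" else paste0("; ", prov))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Synthesize a unimodal count-vs-concentration curve
#'
#' Stands in for a flow-cytometry count table when no experimental
#' supplement is at hand: a skewed unimodal mean curve (gamma-type bump
#' peaking at `peak_fl1h`) plus i.i.d. Gaussian noise truncated at zero.
#' Deterministic for a fixed seed; the generator state of the session is
#' left untouched.
#'
#' @param n_points number of concentrations (>= 5)
#' @param peak_fl1h FL1-H value at the mean-curve peak
#' @param peak_count count at the peak
#' @param noise_sd standard deviation of the additive noise (>= 0)
#' @param seed RNG seed
#' @param fl1h_range range of the FL1-H grid
#' @param shape skewness parameter of the bump (larger = narrower)
#' @return a synthetic `counts_curve`
#' @export
synthesize_counts_curve <- function(n_points = 12, peak_fl1h = 18,
                                    peak_count = 120, noise_sd = 0,
                                    seed = 1, fl1h_range = c(2, 45),
                                    shape = 3) {
  stopifnot(n_points >= 5, noise_sd >= 0, peak_fl1h > 0, peak_count > 0)
  fl1h <- seq(fl1h_range[1], fl1h_range[2], length.out = n_points)
  mean_curve <- peak_count * (fl1h / peak_fl1h)^shape *
    exp(shape * (1 - fl1h / peak_fl1h))
  noise <- local_rng(seed, stats::rnorm(n_points, sd = noise_sd))
  cc <- counts_curve(fl1h, pmax(mean_curve + noise, 0), source = "synthetic")
  attr(cc, "provenance") <- sprintf(
    "n_points=%d peak_fl1h=%g peak_count=%g noise_sd=%g seed=%d shape=%g",
    n_points, peak_fl1h, peak_count, noise_sd, seed, shape)
  cc
}

# evaluate `expr` under a seeded RNG without disturbing the caller's state
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Compare a model curve with a count-vs-concentration data curve
#'
#' Reports shape agreement without any fitting: each curve's argmax on
#' the FL1-H axis, a min-max normalized root-mean-square difference on
#' the overlapping FL1-H range (model linearly interpolated onto the data
#' abscissae), and the sign of each curve's post-peak slope.  The
#' normalization makes the comparison scale-free, as the model's cell
#' count and cytometry counts live on different scales.
#'
#' @param model_curve,data_curve `counts_curve` objects with overlapping
#'   FL1-H ranges
#' @return list: `argmax_model`, `argmax_data`, `nrmse`,
#'   `post_peak_slope_model`, `post_peak_slope_data`, `overlap`
#' @export
compare_model_to_counts <- function(model_curve, data_curve) {
  stopifnot(inherits(model_curve, "counts_curve"),
            inherits(data_curve, "counts_curve"),
            nrow(model_curve) > 0, nrow(data_curve) > 0)
  lo <- max(min(model_curve$fl1h), min(data_curve$fl1h))
  hi <- min(max(model_curve$fl1h), max(data_curve$fl1h))
  if (lo >= hi) stop("disjoint FL1-H ranges")
  keep <- data_curve$fl1h >= lo & data_curve$fl1h <= hi
  xs <- data_curve$fl1h[keep]
  m_i <- stats::approx(model_curve$fl1h, model_curve$count, xout = xs)$y
  d_i <- data_curve$count[keep]
  norm01 <- function(y) {
    r <- range(y)
    if (diff(r) == 0) return(rep(0, length(y)))
    (y - r[1]) / diff(r)
  }
  nrmse <- sqrt(mean((norm01(m_i) - norm01(d_i))^2))
  post_slope <- function(cc) {
    k <- which.max(cc$count)
    if (k >= nrow(cc)) return(NA_real_)
    sign(cc$count[nrow(cc)] - cc$count[k])
  }
  list(argmax_model = model_curve$fl1h[which.max(model_curve$count)],
       argmax_data = data_curve$fl1h[which.max(data_curve$count)],
       nrmse = nrmse,
       post_peak_slope_model = post_slope(model_curve),
       post_peak_slope_data = post_slope(data_curve),
       overlap = c(lo, hi))
}
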