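# Readers/writers and run configuration. Internal units are strictly SI
# (m, s); compass-to-incidence angle conversion happens here, at the I/O
# boundary, and nowhere else.

#' Read wave bulk parameters from delimited text
#'
#' Expected columns: `time` (ISO-8601, UTC), `hs_m`, `tp_s`, `dir_deg`
#' (compass azimuth the waves arrive from), `depth_m`. The compass direction
#' is converted to the incidence angle `theta = (shore_normal - dir_deg)` in
#' radians, wrapped to (-pi, pi]; on a west-facing coast with
#' `shore_normal = 270`, waves from the southwest give `theta > 0` and drive
#' northward (+y) transport.
#'
#' @param path CSV file path.
#' @param shore_normal Seaward shore-normal azimuth, degrees.
#' @return A [wave_records()] data frame.
#' @export
read_waves <- function(path, shore_normal = 270) {
  if (!file.exists(path)) stop("read_waves: file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "hs_m", "tp_s", "dir_deg", "depth_m")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_waves: missing column(s): ", paste(miss, collapse = ", "))
  tm <- as.POSIXct(strptime(d$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(tm)
  if (any(alt))
    tm[alt] <- as.POSIXct(strptime(d$time[alt], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
  bad <- which(is.na(tm))
  if (length(bad))
    stop("read_waves: unparseable time at data row ", bad[1L])
  theta <- (shore_normal - d$dir_deg) * pi / 180
  theta <- ((theta + pi) %% (2 * pi)) - pi
  wave_records(tm, d$hs_m, d$tp_s, theta, d$depth_m)
}

#' Write wave records to delimited text
#'
#' Inverse of [read_waves()]; round-trips at full precision.
#'
#' @param waves A [wave_records()] data frame.
#' @param path Output CSV path.
#' @param shore_normal Seaward shore-normal azimuth, degrees.
#' @export
write_waves <- function(waves, path, shore_normal = 270) {
  dir_deg <- (shore_normal - waves$theta * 180 / pi) %% 360
  d <- data.frame(time = format(waves$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                  hs_m = sprintf("%.17g", waves$hs),
                  tp_s = sprintf("%.17g", waves$tp),
                  dir_deg = sprintf("%.17g", dir_deg),
                  depth_m = sprintf("%.17g", waves$depth))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tracer field to delimited text
#'
#' Two layouts: `"long"` (columns `time`, `y_m`, `c`) and `"wide"` (one row
#' per time, one column per grid node, alongshore coordinates in the header).
#' Values round-trip at full precision through [read_field()].
#'
#' @param field A [tracer_field()].
#' @param path Output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @export
write_field <- function(field, path, layout = c("long", "wide")) {
  stopifnot(inherits(field, "tracer_field"))
  layout <- match.arg(layout)
  ts <- format(field$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (layout == "long") {
    d <- data.frame(time = rep(ts, times = length(field$y)),
                    y_m = rep(field$y, each = length(field$time)),
                    c = sprintf("%.17g", as.vector(field$c)))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    m <- matrix(sprintf("%.17g", field$c), nrow(field$c))
    d <- data.frame(time = ts, m)
    names(d) <- c("time", sprintf("y_%g", field$y))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a tracer field written by [write_field()]
#'
#' @param path CSV path (either layout; detected from the header).
#' @return A [tracer_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("read_field: file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("time", "y_m", "c") %in% names(d))) {
    tm <- as.POSIXct(unique(d$time), tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    y <- sort(unique(d$y_m))
    c <- matrix(NA_real_, length(tm), length(y))
    ti <- match(d$time, unique(d$time)); yi <- match(d$y_m, y)
    c[cbind(ti, yi)] <- d$c
    return(tracer_field(tm, y, c))
  }
  ycols <- grep("^y_", names(d))
  if (names(d)[1L] != "time" || !length(ycols))
    stop("read_field: unrecognized layout in ", path)
  tm <- as.POSIXct(d$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  y <- as.numeric(sub("^y_", "", names(d)[ycols]))
  tracer_field(tm, y, as.matrix(d[, ycols]))
}

# declared bounds for every configurable scalar
.config_bounds <- list(
  L = c(1, 5000), h5m = c(0.5, 20), cd = c(1e-5, 1),
  rho = c(900, 1100), g = c(9, 10),
  k_p = c(0, 1e-2), k_b = c(0, 1e-2), c0 = c(1e-8, 1), c_bac = c(1e-8, 1),
  v_rms = c(1e-3, 2), y_max = c(1000, 2e5), dy = c(1, 5000),
  dt = c(1, 3600), save_dt = c(60, 86400), shore_normal = c(0, 360))

#' Default model configuration
#'
#' Every scalar of the physical model and solver with its default: bathymetry
#' (`L`, `h5m`, `shore_normal`), drag (`cd`, `rho`, `g`), losses (`k_p`,
#' `k_b`), source (`c0`, `c_bac`), the reference RMS velocity `v_rms`, grid
#' (`y_max`, `dy`) and solver (`dt`, `save_dt`), plus the time zone used for
#' advisory calendar days.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    L = 250, h5m = 5, shore_normal = 270,
    cd = 0.01, rho = 1025, g = 9.81,
    k_p = 1.3e-5, k_b = 1.6e-6,
    c0 = 0.2, c_bac = 5e-4, v_rms = 0.1,
    y_max = 29000, dy = 100, dt = 120, save_dt = 3600,
    tz = "UTC"), class = "run_config")
}

#' Read and validate a model configuration
#'
#' A flat YAML file of `key: value` pairs overriding [default_config()].
#' Unknown keys are rejected; every scalar is checked against its declared
#' physical bounds, and violations name the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file (e.g. from
#'   command-line flags).
#' @return A validated `run_config` list.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- unclass(default_config())
  apply_kv <- function(cfg, kv, src) {
    unknown <- setdiff(names(kv), names(cfg))
    if (length(unknown))
      stop("read_config: unknown key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(kv)] <- kv
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_config: file not found: ", path)
    kv <- yaml::read_yaml(path)
    if (!is.null(kv)) cfg <- apply_kv(cfg, kv, path)
  }
  if (!is.null(overrides)) cfg <- apply_kv(cfg, overrides, "overrides")
  for (k in names(.config_bounds)) {
    v <- cfg[[k]]
    b <- .config_bounds[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < b[1] || v > b[2])
      stop(sprintf("read_config: parameter '%s' = %s outside bounds [%g, %g]",
                   k, format(v), b[1], b[2]))
  }
  structure(cfg, class = "run_config")
}

#' Assemble model components from a configuration
#'
#' Convenience splitter turning a `run_config` into the typed component
#' objects the solver and calibrators take.
#'
#' @param cfg A `run_config` from [read_config()] or [default_config()].
#' @return A list with `bathy`, `drag`, `grid`, `loss`, `source`.
#' @export
config_components <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  list(bathy = bathy_config(cfg$L, cfg$h5m, cfg$shore_normal),
       drag = drag_config(cfg$cd, cfg$rho, cfg$g),
       grid = grid_1d(cfg$y_max, cfg$dy),
       loss = loss_params(cfg$k_p, cfg$k_b),
       source = source_config(cfg$c0, cfg$c_bac))
}
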