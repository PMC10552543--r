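# Wave forcing: linear wave theory at a buoy -> surf-zone alongshore current.

#' Bathymetry configuration
#'
#' Geometry of the nearshore strip represented by the 1D model: the mean
#' cross-shore distance `L` from the shoreline to the outer edge of the
#' nearshore (taken at the `h5m` isobath, the offshore limit of the surf zone
#' for the wave climates of interest), and the compass azimuth of the
#' shore-normal used to convert buoy wave directions into incidence angles.
#'
#' @param L Mean shoreline-to-outer-edge distance, m. Must be positive.
#' @param h5m Depth of the nearshore outer edge, m (default 5).
#' @param shore_normal Seaward shore-normal azimuth, degrees clockwise from
#'   north, used only at the I/O boundary when reading compass wave
#'   directions. Default 270 (a west-facing coast with +y to the north).
#' @return An object of class `bathy_config`.
#' @export
bathy_config <- function(L = 250, h5m = 5, shore_normal = 270) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("bathy_config: L must be a positive finite scalar (m)")
  if (!is.numeric(h5m) || length(h5m) != 1L || !is.finite(h5m) || h5m <= 0)
    stop("bathy_config: h5m must be a positive finite scalar (m)")
  structure(list(L = L, h5m = h5m, shore_normal = shore_normal),
            class = "bathy_config")
}

#' Drag / fluid constants
#'
#' @param cd Dimensionless drag coefficient of the linearized bottom-stress
#'   law; the single tunable of the velocity transfer function (see
#'   [tune_cd()]).
#' @param rho Seawater density, kg m^-3.
#' @param g Gravitational acceleration, m s^-2.
#' @return An object of class `drag_config`.
#' @export
drag_config <- function(cd = 0.01, rho = 1025, g = 9.81) {
  if (!is.numeric(cd) || length(cd) != 1L || !is.finite(cd) || cd <= 0)
    stop("drag_config: cd must be a positive finite scalar")
  if (rho <= 0 || g <= 0) stop("drag_config: rho and g must be positive")
  structure(list(cd = cd, rho = rho, g = g), class = "drag_config")
}

#' Wave records
#'
#' Validate a set of wave bulk-parameter records, the sole physical forcing of
#' the model. `theta` is the wave incidence angle measured from the
#' shore-normal in radians; positive `theta` (waves arriving from the +y side
#' of shore-normal, e.g. southerly swell on a west-facing coast) drives
#' positive (northward) alongshore transport.
#'
#' @param time POSIXct timestamps (UTC recommended), strictly increasing.
#' @param hs Significant wave height, m (>= 0).
#' @param tp Peak period, s (> 0).
#' @param theta Wave direction relative to shore-normal, radians, |theta| < pi/2.
#' @param depth Water depth at the observation point, m (> 0).
#' @return A `data.frame` of class `wave_records`.
#' @export
wave_records <- function(time, hs, tp, theta, depth) {
  n <- length(time)
  if (n == 0L) stop("wave_records: empty input")
  if (!inherits(time, "POSIXct")) stop("wave_records: time must be POSIXct")
  if (any(diff(as.numeric(time)) <= 0))
    stop("wave_records: time must be strictly increasing")
  hs <- rep_len(as.numeric(hs), n); tp <- rep_len(as.numeric(tp), n)
  theta <- rep_len(as.numeric(theta), n); depth <- rep_len(as.numeric(depth), n)
  ok <- !is.na(hs) & !is.na(tp) & !is.na(theta) & !is.na(depth)
  if (any(hs[ok] < 0)) stop("wave_records: hs must be >= 0")
  if (any(tp[ok] <= 0)) stop("wave_records: tp must be > 0")
  if (any(depth[ok] <= 0)) stop("wave_records: depth must be > 0")
  if (any(abs(theta[ok]) >= pi / 2))
    stop("wave_records: |theta| must be < pi/2 (incident waves only)")
  structure(data.frame(time = time, hs = hs, tp = tp,
                       theta = theta, depth = depth),
            class = c("wave_records", "data.frame"))
}

#' Linear dispersion relation
#'
#' Solves omega^2 = g k tanh(k h) for the wavenumber k by Newton iteration on
#' the nondimensional product kh (tolerance 1e-10, at most 50 iterations).
#'
#' @param tp Wave period, s (vectorized).
#' @param depth Water depth, m (vectorized).
#' @param g Gravity, m s^-2.
#' @return Wavenumber k, rad m^-1.
#' @export
wave_number <- function(tp, depth, g = 9.81) {
  if (any(tp <= 0, na.rm = TRUE) || any(depth <= 0, na.rm = TRUE))
    stop("wave_number: tp and depth must be positive")
  om <- 2 * pi / tp
  y <- om^2 * depth / g                 # target of x*tanh(x)
  x <- ifelse(y > 1, y, sqrt(y))        # deep / shallow starting guess
  for (i in seq_len(50L)) {
    t <- tanh(x)
    f <- x * t - y
    fp <- t + x * (1 - t^2)
    dx <- f / fp
    x <- x - dx
    if (all(abs(dx) < 1e-10, na.rm = TRUE)) break
  }
  x / depth
}

# cg/c ratio n = 0.5 * (1 + 2kh / sinh(2kh)) from linear theory
.cg_over_c <- function(kh) 0.5 * (1 + 2 * kh / sinh(2 * kh))

#' Off-diagonal wave radiation stress
#'
#' The wave-averaged alongshore flux of cross-shore momentum,
#' `S_xy = E (c_g/c) sin(theta) cos(theta)` with energy density
#' `E = rho g hs^2 / 16`, evaluated from linear wave theory at the observation
#' depth. `S_xy` is conserved as waves shoal until breaking, so it may be
#' computed directly from offshore buoy bulk parameters.
#'
#' @inheritParams wave_records
#' @param rho Seawater density, kg m^-3.
#' @param g Gravity, m s^-2.
#' @return S_xy, N m^-1 (vectorized). Sign follows the sign of `theta`.
#' @export
radiation_stress <- function(hs, tp, theta, depth, rho = 1025, g = 9.81) {
  if (any(hs < 0, na.rm = TRUE)) stop("radiation_stress: hs must be >= 0")
  if (any(tp <= 0, na.rm = TRUE)) stop("radiation_stress: tp must be > 0")
  if (any(depth <= 0, na.rm = TRUE)) stop("radiation_stress: depth must be > 0")
  if (any(abs(theta) >= pi / 2, na.rm = TRUE))
    stop("radiation_stress: |theta| must be < pi/2")
  kh <- wave_number(tp, depth, g) * depth
  e <- rho * g * hs^2 / 16
  e * .cg_over_c(kh) * sin(theta) * cos(theta)
}

#' Transform significant wave height to the nearshore isobath
#'
#' Shoals and refracts a wave record from the observation depth to the `h5m`
#' isobath under linear theory over straight, parallel depth contours:
#' Snell's law conserves the alongshore wavenumber, and the cross-shore energy
#' flux `E c_g cos(theta)` is conserved.
#'
#' @inheritParams wave_records
#' @param h5m Target isobath depth, m.
#' @param g Gravity, m s^-2.
#' @return Significant wave height at `h5m`, m. The refracted incidence angle
#'   is attached as attribute `"theta"`.
#' @export
shoal_to_isobath <- function(hs, tp, theta, depth, h5m = 5, g = 9.81) {
  if (any(depth < h5m, na.rm = TRUE))
    stop("shoal_to_isobath: observation depth shallower than the target ",
         "isobath is not supported")
  om <- 2 * pi / tp
  k1 <- wave_number(tp, depth, g)
  k2 <- wave_number(tp, rep_len(h5m, length(tp)), g)
  c1 <- om / k1; c2 <- om / k2
  cg1 <- .cg_over_c(k1 * depth) * c1
  cg2 <- .cg_over_c(k2 * h5m) * c2
  sin2 <- sin(theta) * c2 / c1          # |sin2| <= |sin(theta)| shoreward
  th2 <- asin(sin2)
  out <- hs * sqrt(cg1 * cos(theta) / (cg2 * cos(th2)))
  out[depth == h5m] <- hs[depth == h5m]
  out[hs == 0] <- 0
  attr(out, "theta") <- th2
  out
}

#' Surf-zone alongshore current from wave forcing
#'
#' The alongshore momentum balance integrated across the surf zone equates
#' the radiation-stress forcing `S_xy / L` with the linearized bottom stress
#' `rho C_d sigma_u v` (small-angle, weak-current approximation, valid when
#' the mean current is much weaker than the wave orbital velocity). With the
#' shallow-water orbital-velocity scale `sigma_u = (H_s,5m / 4) sqrt(g/h_5m)`
#' this gives
#' \deqn{v = \frac{4\,S_{xy}}{\rho\,C_d\,L\,H_{s,5m}}\sqrt{h_{5m}/g}.}
#'
#' @param sxy Off-diagonal radiation stress, N m^-1 (vectorized).
#' @param hs5m Significant wave height at the nearshore isobath, m.
#' @param bathy A [bathy_config()].
#' @param drag A [drag_config()].
#' @return Alongshore velocity, m s^-1, signed (+ = with +y). `v` is
#'   proportional to `S_xy` and to `1/C_d`.
#' @export
alongshore_velocity <- function(sxy, hs5m, bathy, drag) {
  stopifnot(inherits(bathy, "bathy_config"), inherits(drag, "drag_config"))
  if (any(hs5m < 0, na.rm = TRUE)) stop("alongshore_velocity: hs5m must be >= 0")
  bad <- !is.na(hs5m) & !is.na(sxy) & hs5m == 0 & sxy != 0
  if (any(bad))
    stop("alongshore_velocity: hs5m = 0 with nonzero S_xy is inconsistent ",
         "(orbital-velocity scale vanishes)")
  v <- 4 * sxy * sqrt(bathy$h5m / drag$g) /
    (drag$rho * drag$cd * bathy$L * hs5m)
  v[!is.na(sxy) & sxy == 0] <- 0
  v
}

#' Wave-derived alongshore velocity time series
#'
#' Vectorized composition of [radiation_stress()], [shoal_to_isobath()] and
#' [alongshore_velocity()] over a set of wave records. Records with missing
#' values propagate NaN; offshore-traveling records (|theta| >= pi/2), should
#' they appear inside a series, are treated as zero forcing and counted in a
#' message rather than rejected.
#'
#' @param waves A [wave_records()] data frame (time-sorted).
#' @param bathy A [bathy_config()].
#' @param drag A [drag_config()].
#' @return A `velocity_series` object: list with `time` (POSIXct) and `v`
#'   (numeric, m s^-1). Attribute `n_gaps` counts NA records.
#' @export
velocity_series <- function(waves, bathy, drag) {
  if (NROW(waves) == 0L) stop("velocity_series: empty wave input")
  stopifnot(all(c("time", "hs", "tp", "theta", "depth") %in% names(waves)))
  ok <- stats::complete.cases(waves[, c("hs", "tp", "theta", "depth")])
  offsh <- ok & abs(waves$theta) >= pi / 2
  if (any(offsh))
    message("velocity_series: ", sum(offsh),
            " offshore-traveling record(s) treated as zero forcing")
  v <- rep(NA_real_, NROW(waves))
  use <- ok & !offsh
  if (any(use)) {
    w <- waves[use, ]
    sxy <- radiation_stress(w$hs, w$tp, w$theta, w$depth, drag$rho, drag$g)
    hs5 <- shoal_to_isobath(w$hs, w$tp, w$theta, w$depth, bathy$h5m, drag$g)
    vv <- rep(0, nrow(w))
    nz <- w$hs > 0
    vv[nz] <- alongshore_velocity(sxy[nz], as.numeric(hs5)[nz], bathy, drag)
    v[use] <- vv
  }
  v[offsh] <- 0
  if (any(!ok))
    message("velocity_series: ", sum(!ok), " record(s) with missing values; ",
            "NaN propagated")
  v[!ok] <- NaN
  structure(list(time = waves$time, v = v),
            class = "velocity_series", n_gaps = sum(!ok))
}

#' Uniform velocity series from externally supplied values
#'
#' Wraps a measured or modeled alongshore-uniform velocity time series (e.g.
#' current-meter data or a circulation model's domain average) for use as a
#' calibration reference or solver forcing.
#'
#' @param time POSIXct timestamps, strictly increasing.
#' @param v Alongshore velocity, m s^-1, signed.
#' @return A `velocity_series` object.
#' @export
as_velocity_series <- function(time, v) {
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct")
  if (any(diff(as.numeric(time)) <= 0)) stop("time must be strictly increasing")
  if (length(v) != length(time)) stop("v and time lengths differ")
  structure(list(time = time, v = as.numeric(v)), class = "velocity_series")
}

#' Alongshore-varying velocity series (1DC-style forcing)
#'
#' Container for an externally supplied `v(t, y)` field, e.g. extracted from a
#' 3D circulation model or produced by [generate_reference()].
#'
#' @param time POSIXct timestamps, strictly increasing.
#' @param y Alongshore coordinate grid, m.
#' @param v Numeric matrix, `length(time)` rows by `length(y)` columns, m s^-1.
#' @return A `velocity_series` object with a `y` component.
#' @export
velocity_series_varying <- function(time, y, v) {
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct")
  if (any(diff(as.numeric(time)) <= 0)) stop("time must be strictly increasing")
  v <- as.matrix(v)
  if (nrow(v) != length(time) || ncol(v) != length(y))
    stop("v must be a length(time) x length(y) matrix")
  structure(list(time = time, y = as.numeric(y), v = v),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  if (is.matrix(x$v)) {
    cat("Alongshore-varying velocity series: ", length(x$time), " times x ",
        length(x$y), " locations\n", sep = "")
  } else {
    cat("Alongshore velocity series: ", length(x$time), " records\n", sep = "")
  }
  fin <- x$v[is.finite(x$v)]
  cat(sprintf("  range %.3f to %.3f m/s, rms %.3f m/s\n",
              min(fin), max(fin), sqrt(mean(fin^2))))
  invisible(x)
}
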