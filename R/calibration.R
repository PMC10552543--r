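# Calibration of the three tuned parameters: the drag coefficient C_d
# (against a reference velocity series), the physical export rate k_P (from
# the alongshore decay of time-mean tracer), and the boundary concentration
# C_0 (by maximizing downstream Willmott skill). All optimizers are
# deterministic bounded scalar searches (Brent).

#' Calibration result container
#'
#' @param parameter Name of the tuned parameter.
#' @param value Fitted value.
#' @param objective Objective value at the optimum.
#' @param trace Data frame of (parameter, objective) evaluations.
#' @param ... Extra diagnostic fields (e.g. `flagged`, `flatness`).
#' @return An object of class `calibration_result`.
#' @export
calibration_result <- function(parameter, value, objective, trace, ...) {
  if (!is.finite(objective)) stop("calibration_result: objective not finite")
  structure(c(list(parameter = parameter, value = value,
                   objective = objective, trace = trace), list(...)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration of ", x$parameter, ": value = ", format(x$value),
      ", objective = ", format(x$objective), "\n", sep = "")
  if (isTRUE(x$flagged)) cat("  FLAGGED: ", x$flag_reason, "\n", sep = "")
  invisible(x)
}

#' Tune the drag coefficient against a reference velocity series
#'
#' Finds the `C_d` minimizing the RMS misfit between the wave-derived
#' alongshore velocity and a reference series (e.g. the domain-averaged
#' nearshore velocity of a circulation model, or current-meter data),
#' evaluated on the overlapping time span. Because the wave-derived velocity
#' is exactly proportional to `1/C_d`, the forcing series is computed once at
#' `C_d = 1` and the misfit minimized by bounded scalar search.
#'
#' @param waves A [wave_records()] data frame.
#' @param v_ref A `velocity_series` reference (uniform).
#' @param bathy A [bathy_config()].
#' @param bounds Search interval for `C_d` (default `c(1e-4, 1)`).
#' @param drag Optional [drag_config()] supplying `rho` and `g`.
#' @return A [calibration_result()] with the fitted `cd`, RMS misfit at the
#'   optimum, and a log-spaced search trace.
#' @export
tune_cd <- function(waves, v_ref, bathy, bounds = c(1e-4, 1),
                    drag = drag_config()) {
  stopifnot(inherits(v_ref, "velocity_series"), !is.matrix(v_ref$v))
  base <- velocity_series(waves, bathy,
                          drag_config(cd = 1, rho = drag$rho, g = drag$g))
  bt <- as.numeric(base$time); rt <- as.numeric(v_ref$time)
  lo <- max(min(bt), min(rt)); hi <- min(max(bt), max(rt))
  if (hi <= lo) stop("tune_cd: no overlap between wave forcing and reference")
  sel <- rt >= lo & rt <= hi & is.finite(v_ref$v)
  if (!any(sel)) stop("tune_cd: no usable reference samples in the overlap")
  vb <- stats::approx(bt, base$v, xout = rt[sel])$y
  vr <- v_ref$v[sel]
  ok <- is.finite(vb)
  vb <- vb[ok]; vr <- vr[ok]
  if (all(vb == 0)) stop("tune_cd: flat objective (all-zero wave forcing)")
  obj <- function(cd) sqrt(mean((vb / cd - vr)^2))
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-10)
  grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = 25L)
  calibration_result("cd", opt$minimum, opt$objective,
                     data.frame(cd = grid, rms = vapply(grid, obj, 0)),
                     n_overlap = length(vr))
}

#' Estimate the physical export rate from alongshore tracer decay
#'
#' The total linear loss rate is read off the alongshore decay of time-mean
#' tracer: the time-averaged dilution of tracer with distance from the source
#' (the slope of `log` time-mean concentration versus `y`, fit by ordinary
#' least squares over `fit_range`), scaled by the root-mean-square alongshore
#' velocity. Subtracting the biological inactivation rate `k_b` leaves the
#' physical export rate `k_p`.
#'
#' @param c_ref A [tracer_field()] reference.
#' @param v_rms Root-mean-square alongshore velocity, m s^-1 (default 0.1).
#' @param k_b Biological inactivation rate to subtract, s^-1.
#' @param fit_range y-interval (m) for the slope fit; the default 5-25 km
#'   avoids source-adjacent and far-boundary cells.
#' @return A [calibration_result()] with the estimated `k_p`, the residual
#'   RMS of the log-linear fit, the fitted profile as trace, and `k_total`.
#'   A negative `k_p` (loss slower than `k_b`) is flagged, not clamped.
#' @export
estimate_kp <- function(c_ref, v_rms = 0.1, k_b = 1.6e-6,
                        fit_range = c(5000, 25000)) {
  stopifnot(inherits(c_ref, "tracer_field"))
  if (v_rms <= 0) stop("estimate_kp: v_rms must be positive")
  cbar <- colMeans(c_ref$c)
  sel <- c_ref$y >= fit_range[1] & c_ref$y <= fit_range[2]
  if (sum(sel) < 3L) stop("estimate_kp: fewer than 3 locations in fit_range")
  if (any(cbar[sel] <= 0))
    stop("estimate_kp: time-mean concentration must be positive over fit_range")
  y <- c_ref$y[sel]; lc <- log(cbar[sel])
  fit <- stats::lm(lc ~ y)
  b <- -stats::coef(fit)[[2L]]          # alongshore decay rate, m^-1
  k_total <- b * v_rms
  k_p <- k_total - k_b
  res <- calibration_result(
    "k_p", k_p, sqrt(mean(stats::residuals(fit)^2)),
    data.frame(y = y, log_mean_c = lc, fitted = stats::fitted(fit)),
    k_total = k_total,
    flagged = k_p < 0,
    flag_reason = if (k_p < 0) "total loss rate below k_b (negative k_p)"
    else NULL)
  res
}

#' Tune the boundary concentration by maximizing downstream skill
#'
#' The transport equation is linear in concentration, so the model solution
#' scales multiplicatively with `c0`. The model is run once with `c0 = 1` and
#' the `c0` maximizing the mean Willmott skill against the reference over
#' alongshore locations `y > skill_min_y` (default 5 km, where the beaches of
#' interest are) is found by bounded search on `log10(c0)`.
#'
#' @param waves A [wave_records()] data frame covering the reference period.
#' @param c_ref A [tracer_field()] reference on the model grid.
#' @param grid A [grid_1d()].
#' @param loss A [loss_params()].
#' @param bathy A [bathy_config()].
#' @param drag A [drag_config()] (with the calibrated `cd`).
#' @param bounds Search interval for `c0` (default `c(1e-3, 1)`).
#' @param skill_min_y Locations with `y` strictly greater than this (m) enter
#'   the skill average.
#' @param dt,save_dt Solver and output cadence, s, passed to [run_transport()].
#' @return A [calibration_result()] with the fitted `c0`, mean Willmott skill
#'   at the optimum, a log-spaced scan trace, and a `flatness` diagnostic:
#'   the skill at `c0` a half-decade below and above the optimum (the skill
#'   surface is expected to be flat within an order of magnitude).
#' @export
tune_c0 <- function(waves, c_ref, grid, loss, bathy, drag,
                    bounds = c(1e-3, 1), skill_min_y = 5000,
                    dt = 120, save_dt = 3600) {
  stopifnot(inherits(c_ref, "tracer_field"))
  sel <- c_ref$y > skill_min_y
  if (!any(sel)) stop("tune_c0: empty skill range (no y > skill_min_y)")
  if (all(c_ref$c == 0))
    stop("tune_c0: degenerate objective (reference identically zero)")
  vel <- velocity_series(waves, bathy, drag)
  base <- run_transport(vel, grid, loss, source_config(c0 = 1),
                        dt = dt, save_dt = save_dt)
  if (length(base$time) != length(c_ref$time) ||
      any(as.numeric(base$time) != as.numeric(c_ref$time)))
    stop("tune_c0: reference field does not cover the tuning window at the ",
         "model output cadence")
  cols <- which(sel)
  skill <- function(c0) {
    w <- vapply(cols, function(j)
      suppressMessages(willmott_skill(c0 * base$c[, j], c_ref$c[, j])), 0)
    mean(w)
  }
  obj <- function(l10) skill(10^l10)
  opt <- stats::optimize(obj, interval = log10(bounds), maximum = TRUE,
                         tol = 1e-6)
  c0_hat <- 10^opt$maximum
  grid10 <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = 25L)
  calibration_result(
    "c0", c0_hat, opt$objective,
    data.frame(c0 = grid10, mean_wss = vapply(grid10, skill, 0)),
    flatness = data.frame(
      c0 = c0_hat * 10^c(-0.5, 0, 0.5),
      mean_wss = c(skill(c0_hat * 10^-0.5), opt$objective,
                   skill(c0_hat * 10^0.5))))
}
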