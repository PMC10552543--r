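# 1D alongshore advection-loss solver: first-order upwind advection with
# exact exponential decay by operator splitting. No explicit diffusion term;
# alongshore diffusivity is neglected and upwind's numerical diffusion is
# accepted (and characterized by the convergence tests).

#' Alongshore model grid
#'
#' Regular 1D grid from the source at `y = 0` to `y_max` (default 29 km, the
#' stretch of coastline the model represents).
#'
#' @param y_max Domain length, m.
#' @param dy Grid spacing, m.
#' @return An object of class `grid_1d` with components `y`, `dy`, `n`.
#' @export
grid_1d <- function(y_max = 29000, dy = 100) {
  if (dy <= 0) stop("grid_1d: dy must be positive")
  if (y_max < dy) stop("grid_1d: y_max must be at least dy")
  y <- seq(0, y_max, by = dy)
  structure(list(y = y, dy = dy, n = length(y)), class = "grid_1d")
}

#' Linear loss parameters
#'
#' Two constant, alongshore-uniform linear losses act on the tracer: `k_p`,
#' physical export of tracer from the nearshore to the inner shelf (rip
#' currents and other cross-shelf exchange, parametrized as monotonic decay),
#' and `k_b`, biological inactivation (pathogen die-off; the default matches
#' norovirus mortality). Export dominates here: `k_p` is an order of
#' magnitude larger than `k_b`.
#'
#' @param k_p Physical export rate, s^-1 (default 1.3e-5).
#' @param k_b Biological inactivation rate, s^-1 (default 1.6e-6).
#' @return An object of class `loss_params`.
#' @export
loss_params <- function(k_p = 1.3e-5, k_b = 1.6e-6) {
  if (k_p < 0 || k_b < 0) stop("loss_params: rates must be >= 0")
  structure(list(k_p = k_p, k_b = k_b), class = "loss_params")
}

#' Tracer source and advisory threshold
#'
#' The tracer enters through a Dirichlet boundary at `y = 0`: concentration is
#' held at `c0` whenever flow at the boundary is directed into the domain.
#' `c_bac` is the beach-advisory concentration threshold (dimensionless,
#' source-relative), corresponding to a 10% swimmer-illness likelihood.
#'
#' @param c0 Boundary concentration, dimensionless (> 0).
#' @param c_bac Advisory threshold, dimensionless (> 0, default 5e-4).
#' @return An object of class `source_config`.
#' @export
source_config <- function(c0 = 0.2, c_bac = 5e-4) {
  if (c0 <= 0) stop("source_config: c0 must be positive")
  if (c_bac <= 0) stop("source_config: c_bac must be positive")
  structure(list(c0 = c0, c_bac = c_bac), class = "source_config")
}

#' Tracer concentration field
#'
#' @param time POSIXct output timestamps.
#' @param y Alongshore grid, m.
#' @param c Numeric matrix, `length(time)` x `length(y)`, nonnegative.
#' @return An object of class `tracer_field`.
#' @export
tracer_field <- function(time, y, c) {
  c <- as.matrix(c)
  if (nrow(c) != length(time) || ncol(c) != length(y))
    stop("tracer_field: c must be length(time) x length(y)")
  if (any(!is.finite(c))) stop("tracer_field: concentrations must be finite")
  if (any(c < 0)) stop("tracer_field: concentrations must be nonnegative")
  structure(list(time = time, y = as.numeric(y), c = c),
            class = "tracer_field")
}

#' @export
print.tracer_field <- function(x, ...) {
  cat("Tracer field: ", length(x$time), " times x ", length(x$y),
      " alongshore locations (y ", min(x$y) / 1000, "-", max(x$y) / 1000,
      " km)\n", sep = "")
  cat(sprintf("  concentration range %.3g to %.3g\n", min(x$c), max(x$c)))
  invisible(x)
}

# One unvalidated solver step: upwind advection then exact decay.
# c: state vector; v: scalar or per-node vector; cfl = dt/dy; dec = exp(-k dt).
.step_core <- function(c, v, cfl, dec, c0) {
  n <- length(c)
  if (length(v) == 1L) {
    if (v > 0) {
      cn <- c - (v * cfl) * (c - c[c(1L, seq_len(n - 1L))])
      cn <- cn * dec
      cn[1L] <- c0                       # Dirichlet on inflow
    } else if (v < 0) {
      cr <- c[c(seq_len(n - 1L) + 1L, n)]  # zero-gradient ghost at y_max
      cn <- (c - (v * cfl) * (cr - c)) * dec
    } else {
      cn <- c * dec
    }
    return(cn)
  }
  cl <- c[c(1L, seq_len(n - 1L))]
  cr <- c[c(seq_len(n - 1L) + 1L, n)]
  grad <- c - cl
  neg <- v < 0
  if (any(neg)) grad[neg] <- cr[neg] - c[neg]  # incl. zero-gradient outflow at y=0
  if (v[n] < 0) grad[n] <- 0                   # inflow at y_max: zero-gradient
  cn <- (c - cfl * v * grad) * dec
  if (v[1L] > 0) cn[1L] <- c0
  cn
}

#' Advance the tracer one time step
#'
#' First-order upwind advection followed by exact linear decay by the factor
#' `exp(-(k_p + k_b) dt)` (operator splitting, so the decay carries no
#' integration error). The boundary at `y = 0` is held at `c0` on strict
#' inflow and is zero-gradient on outflow; `y_max` is zero-gradient. Upwind
#' differencing under the CFL condition preserves nonnegativity and, with a
#' single source, boundedness by `c0`.
#'
#' @param c Concentration state vector on the grid nodes (>= 0).
#' @param v Alongshore velocity, m s^-1: a scalar (uniform mode) or one value
#'   per grid node (varying mode).
#' @param dt Time step, s.
#' @param grid A [grid_1d()].
#' @param loss A [loss_params()].
#' @param source A [source_config()].
#' @return The concentration state after one step.
#' @export
tracer_step <- function(c, v, dt, grid, loss, source) {
  stopifnot(inherits(grid, "grid_1d"), inherits(loss, "loss_params"),
            inherits(source, "source_config"))
  if (length(c) != grid$n) stop("tracer_step: state length must match grid")
  if (any(c < 0)) stop("tracer_step: negative concentrations in input state")
  vmax <- max(abs(v))
  if (vmax * dt / grid$dy > 1 + 1e-12)
    stop(sprintf(paste0("tracer_step: CFL violated: max|v| = %.3f m/s needs ",
                        "dt <= %.1f s at dy = %g m (got dt = %g s)"),
                 vmax, grid$dy / vmax, grid$dy, dt))
  if (length(v) != 1L && length(v) != grid$n)
    stop("tracer_step: v must be scalar or one value per node")
  .step_core(c, v, dt / grid$dy, exp(-(loss$k_p + loss$k_b) * dt), source$c0)
}

#' Run the 1D tracer transport model
#'
#' Integrates the alongshore advection-loss equation
#' \deqn{\partial C/\partial t + v\,\partial C/\partial y = -(k_P + k_B)\,C}
#' over `[t0, t1]`, forced either by an alongshore-uniform wave-derived
#' velocity `v(t)` (uniform mode, "1D") or by an externally supplied
#' alongshore-varying `v(t, y)` (varying mode, "1DC"). Forcing is linearly
#' interpolated to solver steps; output is saved at `save_dt` cadence
#' (default hourly).
#'
#' @param velocity A `velocity_series` (from [velocity_series()] or
#'   [velocity_series_varying()]; a varying series must be on the model grid).
#' @param grid A [grid_1d()].
#' @param loss A [loss_params()].
#' @param source A [source_config()].
#' @param t0,t1 POSIXct start and end times; default to the forcing range.
#' @param dt Solver time step, s (default 120; must satisfy the CFL condition
#'   `max|v| dt / dy <= 1`).
#' @param save_dt Output cadence, s; must be a multiple of `dt`.
#' @param c_init Initial concentration state (default all zero).
#' @param max_gap Longest tolerated gap in the forcing time base, s.
#' @return A [tracer_field()] including the initial state at `t0`; the
#'   resolved run parameters are attached as attribute `run_params`.
#' @export
run_transport <- function(velocity, grid, loss, source,
                          t0 = NULL, t1 = NULL, dt = 120, save_dt = 3600,
                          c_init = NULL, max_gap = 6 * 3600) {
  stopifnot(inherits(velocity, "velocity_series"), inherits(grid, "grid_1d"),
            inherits(loss, "loss_params"), inherits(source, "source_config"))
  varying <- is.matrix(velocity$v)
  if (varying && !isTRUE(all.equal(velocity$y, grid$y)))
    stop("run_transport: varying velocity series must be on the model grid")
  ft <- as.numeric(velocity$time)
  gaps <- diff(ft)
  if (length(gaps) && max(gaps) > max_gap)
    stop(sprintf("run_transport: forcing gap of %.0f s exceeds max_gap = %.0f s",
                 max(gaps), max_gap))
  if (is.null(t0)) t0 <- velocity$time[1L]
  if (is.null(t1)) t1 <- velocity$time[length(velocity$time)]
  tn0 <- as.numeric(t0); tn1 <- as.numeric(t1)
  if (tn1 <= tn0) stop("run_transport: t1 must be after t0")
  if (tn0 < ft[1L] || tn1 > ft[length(ft)])
    stop("run_transport: forcing does not cover [t0, t1]")
  nsteps <- round((tn1 - tn0) / dt)
  if (abs(nsteps * dt - (tn1 - tn0)) > 1e-6)
    stop("run_transport: (t1 - t0) must be a multiple of dt")
  every <- round(save_dt / dt)
  if (abs(every * dt - save_dt) > 1e-6 || every < 1L)
    stop("run_transport: save_dt must be a positive multiple of dt")

  step_t <- tn0 + dt * (0:(nsteps - 1L))   # velocity taken at step start
  if (varying) {
    idx <- findInterval(step_t, ft, rightmost.closed = TRUE)
    w <- (step_t - ft[idx]) / (ft[pmin(idx + 1L, length(ft))] - ft[idx])
    w[!is.finite(w)] <- 0
    vmax <- max(abs(velocity$v))
  } else {
    vstep <- stats::approx(ft, velocity$v, xout = step_t)$y
    if (anyNA(vstep))
      stop("run_transport: missing values in interpolated forcing; fill gaps ",
           "before running")
    vmax <- max(abs(vstep))
  }
  if (vmax * dt / grid$dy > 1 + 1e-12)
    stop(sprintf(paste0("run_transport: CFL violated: max|v| = %.3f m/s needs ",
                        "dt <= %.1f s at dy = %g m (got dt = %g s)"),
                 vmax, grid$dy / vmax, grid$dy, dt))

  cfl <- dt / grid$dy
  dec <- exp(-(loss$k_p + loss$k_b) * dt)
  c <- if (is.null(c_init)) numeric(grid$n) else {
    if (length(c_init) != grid$n || any(c_init < 0))
      stop("run_transport: c_init must be a nonnegative state on the grid")
    as.numeric(c_init)
  }
  nsave <- nsteps %/% every
  out <- matrix(0, nsave + 1L, grid$n)
  out[1L, ] <- c
  save_i <- 1L
  for (s in seq_len(nsteps)) {
    if (varying) {
      i <- idx[s]
      vrow <- if (i >= nrow(velocity$v)) velocity$v[nrow(velocity$v), ]
      else velocity$v[i, ] + w[s] * (velocity$v[i + 1L, ] - velocity$v[i, ])
      if (anyNA(vrow))
        stop("run_transport: missing values in varying forcing")
      c <- .step_core(c, vrow, cfl, dec, source$c0)
    } else {
      c <- .step_core(c, vstep[s], cfl, dec, source$c0)
    }
    if (s %% every == 0L) {
      save_i <- save_i + 1L
      out[save_i, ] <- c
    }
  }
  if (min(out) < 0)
    stop("run_transport: internal error: negative concentration produced")
  tf <- tracer_field(t0 + save_dt * (0:nsave), grid$y, out)
  attr(tf, "run_params") <- list(
    mode = if (varying) "varying" else "uniform", dt = dt, save_dt = save_dt,
    dy = grid$dy, y_max = max(grid$y), k_p = loss$k_p, k_b = loss$k_b,
    c0 = source$c0, t0 = t0, t1 = t1)
  tf
}

#' Analytic steady-state concentration profile
#'
#' For constant positive alongshore velocity the advection-loss equation has
#' the steady solution `C(y) = c0 * exp(-(k_p + k_b) * y / v)`, with e-folding
#' length `v / (k_p + k_b)`. Used as the solver's analytic oracle.
#'
#' @param v Constant alongshore velocity, m s^-1 (> 0).
#' @param loss A [loss_params()].
#' @param source A [source_config()].
#' @param grid A [grid_1d()].
#' @return Concentration profile on `grid$y`.
#' @export
steady_state_analytic <- function(v, loss, source, grid) {
  stopifnot(inherits(grid, "grid_1d"), inherits(loss, "loss_params"),
            inherits(source, "source_config"))
  if (length(v) != 1L || v <= 0)
    stop("steady_state_analytic: v must be a positive scalar")
  source$c0 * exp(-(loss$k_p + loss$k_b) * grid$y / v)
}
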