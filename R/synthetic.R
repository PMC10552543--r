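# Seeded synthetic inputs: a two-season wave climate emulating the regional
# pattern (persistent summer southerly swell driving northward flow; winter
# northwesterly waves driving southward flow with episodic south swells), and
# pseudo-reference nearshore velocity/tracer fields with known ground-truth
# parameters standing in for a 3D circulation hindcast.

#' Synthetic wave-climate specification
#'
#' Defaults describe one year of hourly records at a 10 m buoy on a
#' west-facing coast. Summer (June 1 to October 1): modest long-period swell
#' arriving from south of shore-normal (`theta > 0`). Winter: larger,
#' shorter-period waves from north of shore-normal (`theta < 0`) with
#' occasional multi-day south-swell events that reverse the flow. Hourly
#' variability is smooth (AR(1)) so synoptic wave events persist for days.
#'
#' @param start,end Date-like start (inclusive) and end (exclusive) of the
#'   hourly series.
#' @param summer_window Month-day strings delimiting the summer season.
#' @param summer,winter Lists of seasonal means: `hs` (m), `tp` (s), `theta`
#'   (radians from shore-normal).
#' @param noise List of variability scales: `hs` (lognormal sd of log hs),
#'   `theta` (radians), `tp` (s), and `ar`, the hourly AR(1) coefficient.
#' @param south_swell List describing winter reversal events: `prob`
#'   (per-hour start probability), `duration` (h), `theta` (radians), and
#'   `hs_factor`.
#' @param depth Buoy depth, m.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `climate_spec`.
#' @export
climate_spec <- function(start = "2018-01-01", end = "2019-01-01",
                         summer_window = c("06-01", "10-01"),
                         summer = list(hs = 0.8, tp = 13, theta = 15 * pi / 180),
                         winter = list(hs = 1.1, tp = 11, theta = -12 * pi / 180),
                         noise = list(hs = 0.3, theta = 8 * pi / 180,
                                      tp = 1.5, ar = 0.98),
                         south_swell = list(prob = 0.0015, duration = 60,
                                            theta = 18 * pi / 180,
                                            hs_factor = 1.3),
                         depth = 10, seed = 1L) {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (is.na(start) || is.na(end) || end <= start)
    stop("climate_spec: invalid date range")
  for (s in list(summer, winter))
    if (s$hs < 0 || s$tp <= 0 || abs(s$theta) >= pi / 2)
      stop("climate_spec: seasonal means out of physical range")
  if (any(unlist(noise[c("hs", "theta", "tp")]) < 0) ||
      noise$ar < 0 || noise$ar >= 1)
    stop("climate_spec: noise scales must be nonnegative, ar in [0, 1)")
  structure(list(start = start, end = end, summer_window = summer_window,
                 summer = summer, winter = winter, noise = noise,
                 south_swell = south_swell, depth = depth, seed = seed),
            class = "climate_spec")
}

# standardized AR(1) series, unit marginal variance
.ar1 <- function(n, rho) {
  if (rho == 0) return(stats::rnorm(n))
  as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - rho^2)),
                           rho, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Generate a synthetic seasonal wave climate
#'
#' Hourly [wave_records()] drawn from a [climate_spec()]; fully reproducible
#' under the spec's seed. With all noise scales zero and no south-swell
#' events the records are constant within each season.
#'
#' @param spec A [climate_spec()].
#' @return A [wave_records()] data frame.
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  set.seed(spec$seed)
  time <- seq(spec$start, spec$end - 3600, by = 3600)
  n <- length(time)
  md <- format(time, "%m-%d", tz = "UTC")
  summer <- md >= spec$summer_window[1] & md < spec$summer_window[2]
  hs_mu <- ifelse(summer, spec$summer$hs, spec$winter$hs)
  tp_mu <- ifelse(summer, spec$summer$tp, spec$winter$tp)
  th_mu <- ifelse(summer, spec$summer$theta, spec$winter$theta)

  rho <- spec$noise$ar
  hs <- hs_mu * exp(spec$noise$hs * .ar1(n, rho) - spec$noise$hs^2 / 2)
  th <- th_mu + spec$noise$theta * .ar1(n, rho)
  tp <- tp_mu + spec$noise$tp * .ar1(n, rho)

  # winter south-swell events: multi-day reversals to positive theta
  ss <- spec$south_swell
  if (!is.null(ss) && ss$prob > 0) {
    starts <- which(!summer & stats::runif(n) < ss$prob)
    event <- rep(FALSE, n)
    for (s in starts) event[s:min(n, s + ss$duration - 1L)] <- TRUE
    event <- event & !summer
    th[event] <- ss$theta + spec$noise$theta * .ar1(n, rho)[event]
    hs[event] <- hs[event] * ss$hs_factor
  }

  hs <- pmax(hs, 0.05)
  tp <- pmin(pmax(tp, 5), 22)
  th <- pmin(pmax(th, -75 * pi / 180), 75 * pi / 180)
  wave_records(time, hs, tp, th, spec$depth)
}

#' Synthetic reference-field specification
#'
#' Ground-truth parameters for the pseudo-reference nearshore fields: the
#' embedded drag coefficient, loss rates and boundary concentration, plus the
#' structure of the alongshore velocity perturbation (a smooth random
#' modulation with a prescribed correlation length, and a localized slowdown
#' at a mock inlet, mimicking flow disruption by an estuary mouth) and
#' multiplicative lognormal observation noise on concentration.
#'
#' @param cd,k_p,k_b,c0 True physical parameters embedded in the reference.
#' @param perturb_amp Standard deviation of the smooth alongshore modulation
#'   (0 disables it).
#' @param perturb_length Alongshore correlation length of the modulation, m.
#' @param inlet_y,inlet_amp,inlet_width Position (m), fractional depth and
#'   Gaussian width (m) of the localized slowdown (amp 0 disables; amp > 1
#'   produces local reversals).
#' @param obs_noise_sd Lognormal sigma of multiplicative observation noise on
#'   concentration (0 disables).
#' @param seed Integer seed.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(cd = 0.01, k_p = 1.3e-5, k_b = 1.6e-6, c0 = 0.2,
                           perturb_amp = 0.25, perturb_length = 3000,
                           inlet_y = 10000, inlet_amp = 0.5,
                           inlet_width = 1500, obs_noise_sd = 0.3,
                           seed = 1L) {
  if (cd <= 0 || k_p < 0 || k_b < 0 || c0 <= 0)
    stop("reference_spec: physical parameters out of range")
  if (perturb_amp < 0 || obs_noise_sd < 0 || perturb_length <= 0 ||
      inlet_width <= 0)
    stop("reference_spec: perturbation scales must be nonnegative")
  structure(list(cd = cd, k_p = k_p, k_b = k_b, c0 = c0,
                 perturb_amp = perturb_amp, perturb_length = perturb_length,
                 inlet_y = inlet_y, inlet_amp = inlet_amp,
                 inlet_width = inlet_width, obs_noise_sd = obs_noise_sd,
                 seed = seed),
            class = "reference_spec")
}

#' Generate pseudo-reference nearshore fields
#'
#' Builds an alongshore-varying velocity field `v(t, y)` by modulating the
#' wave-derived uniform current (computed with the spec's true drag
#' coefficient) with a static alongshore shape — a smooth random component
#' plus a localized inlet slowdown — then solves the transport equation in
#' varying mode with the true loss rates and boundary concentration, and
#' finally applies multiplicative lognormal observation noise to the tracer.
#' With zero perturbation and zero noise the reference equals the uniform-
#' mode run exactly.
#'
#' @param spec A [reference_spec()].
#' @param climate A [wave_records()] data frame (e.g. [generate_climate()]).
#' @param grid A [grid_1d()].
#' @param bathy A [bathy_config()].
#' @param rho,g Fluid constants for the embedded [drag_config()].
#' @param dt,save_dt Solver step and output cadence, s.
#' @return A list with `velocity` (varying `velocity_series`), `tracer` (the
#'   noisy reference [tracer_field()]), and `modulation` (the alongshore
#'   shape applied to the velocity).
#' @export
generate_reference <- function(spec, climate, grid = grid_1d(),
                               bathy = bathy_config(), rho = 1025, g = 9.81,
                               dt = 120, save_dt = 3600) {
  stopifnot(inherits(spec, "reference_spec"), inherits(grid, "grid_1d"))
  set.seed(spec$seed + 1L)
  drag <- drag_config(cd = spec$cd, rho = rho, g = g)
  v1d <- velocity_series(climate, bathy, drag)
  if (anyNA(v1d$v))
    stop("generate_reference: climate contains gaps")

  m <- rep(1, grid$n)
  if (spec$perturb_amp > 0) {
    half <- 3 * ceiling(spec$perturb_length / grid$dy)
    kern <- exp(-0.5 * ((-half:half) * grid$dy / spec$perturb_length)^2)
    z <- stats::rnorm(grid$n + 2L * half)
    s <- as.numeric(stats::filter(z, kern / sum(kern), sides = 2L))
    s <- s[(half + 1L):(half + grid$n)]
    s <- (s - mean(s)) / stats::sd(s)
    m <- m + spec$perturb_amp * s
  }
  if (spec$inlet_amp > 0)
    m <- m - spec$inlet_amp *
      exp(-((grid$y - spec$inlet_y) / spec$inlet_width)^2)

  vmat <- outer(v1d$v, m)
  vel <- velocity_series_varying(v1d$time, grid$y, vmat)
  # dt is an upper bound: the perturbation can amplify the current, so the
  # step is reduced (among divisors of save_dt) until CFL holds with margin
  divisors <- Filter(function(d) save_dt %% d == 0, seq_len(dt))
  ok <- divisors[max(abs(vmat)) * divisors / grid$dy <= 0.95]
  if (!length(ok))
    stop("generate_reference: perturbed velocity too fast for any solver ",
         "step; refine the grid or reduce the perturbation")
  tf <- run_transport(vel, grid, loss_params(spec$k_p, spec$k_b),
                      source_config(c0 = spec$c0), dt = max(ok),
                      save_dt = save_dt)
  if (spec$obs_noise_sd > 0) {
    zn <- matrix(stats::rnorm(length(tf$c)), nrow(tf$c))
    tf$c <- tf$c * exp(spec$obs_noise_sd * zn - spec$obs_noise_sd^2 / 2)
  }
  list(velocity = vel, tracer = tf, modulation = m)
}
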