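# Shared fixtures and independent oracles used across the suite.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# hourly timestamp sequence of length n
hours <- function(n, start = "2018-01-01") utc(start) + 3600 * (0:(n - 1))

# constant uniform velocity forcing spanning n_hours
const_velocity <- function(v, n_hours, start = "2018-01-01") {
  as_velocity_series(hours(n_hours, start), rep(v, n_hours))
}

# Independent dispersion oracle: bisection via uniroot on
# omega^2 = g k tanh(k h), no shared code with wave_number().
k_uniroot <- function(tp, depth, g = 9.81) {
  om <- 2 * pi / tp
  f <- function(k) g * k * tanh(k * depth) - om^2
  stats::uniroot(f, c(1e-8, 10), tol = 1e-14)$root
}

cg_uniroot <- function(tp, depth, g = 9.81) {
  k <- k_uniroot(tp, depth, g)
  c <- (2 * pi / tp) / k
  0.5 * (1 + 2 * k * depth / sinh(2 * k * depth)) * c
}

# Brute-force weekly-sampling advisory oracle: walks the calendar
# explicitly, one location at a time. Independent of the package's
# vectorized scheduling.
brute_weekly <- function(truth, sampling_hour) {
  nt <- length(truth$time)
  days <- as.Date(format(truth$time, "%Y-%m-%d", tz = "UTC"))
  ud <- sort(unique(days))
  a <- matrix(FALSE, length(ud), ncol(truth$x))
  for (j in seq_len(ncol(truth$x))) {
    for (s in seq_len(nt)) {
      h <- s - 1L
      if (h %% 168L != sampling_hour) next
      result <- truth$x[s, j]
      for (d in seq_along(ud)) {
        lag <- as.integer(ud[d] - days[s])
        if (lag >= 1L && lag <= 7L) a[d, j] <- result
      }
    }
  }
  structure(list(day = ud, y = truth$y, a = a), class = "daily_advisory")
}

# small synthetic hourly exceedance field with scattered plumes
toy_truth <- function(n_hours = 5 * 168, ny = 3, p = 0.08, seed = 42,
                      start = "2018-01-01") {
  set.seed(seed)
  x <- matrix(runif(n_hours * ny) < p, n_hours, ny)
  # make exceedances persist a few hours so days correlate
  for (j in seq_len(ny)) x[, j] <- as.logical(stats::filter(
    x[, j], rep(1, 4), sides = 1)) %in% TRUE
  structure(list(time = hours(n_hours, start), y = (1:ny) * 1000, x = x),
            class = "binary_field")
}
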