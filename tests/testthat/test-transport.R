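# Upwind advection-loss solver: exactness properties, boundary handling,
# analytic steady state, and conservation.

grid_s <- grid_1d(y_max = 5000, dy = 100)   # small grid for step-level tests
loss0 <- loss_params(0, 0)
src <- source_config(c0 = 1)

test_that("step is the identity with no flow and no loss", {
  c <- runif(grid_s$n)
  expect_equal(tracer_step(c, 0, 60, grid_s, loss0, src), c)
})

test_that("decay splitting is exact: v = 0 decays by exp(-k dt) everywhere", {
  loss <- loss_params(1e-5, 4.6e-6)
  k <- loss$k_p + loss$k_b
  c <- rep(1, grid_s$n)
  out <- tracer_step(c, 0, 120, grid_s, loss, src)
  expect_equal(out, rep(exp(-k * 120), grid_s$n), tolerance = 1e-15)
})

# Pulse oracles run with southward flow so the inflow source at y = 0 stays
# inactive and pure advection can be isolated.
test_that("pulse advection at CFL = 1 is an exact shift", {
  c <- numeric(grid_s$n); c[20] <- 1
  v <- -0.5; dt <- grid_s$dy / abs(v)
  out <- tracer_step(c, v, dt, grid_s, loss0, src)
  want <- numeric(grid_s$n); want[19] <- 1
  expect_equal(out, want)
})

test_that("pulse centroid advances v dt per step; interior mass conserved", {
  c <- numeric(grid_s$n); c[30:40] <- dnorm(30:40, 35, 2)
  v <- -0.4; dt <- 100
  m0 <- sum(c); y0 <- sum(grid_s$y * c) / m0
  out <- c
  for (i in 1:20) out <- tracer_step(out, v, dt, grid_s, loss0, src)
  expect_equal(sum(out), m0, tolerance = 1e-14)
  expect_equal(sum(grid_s$y * out) / sum(out), y0 + 20 * v * dt,
               tolerance = 1e-10)
})

test_that("CFL violations are rejected with the required dt", {
  expect_error(tracer_step(numeric(grid_s$n), 1.0, 200, grid_s, loss0, src),
               "CFL")
  expect_error(tracer_step(numeric(grid_s$n), 1.0, 200, grid_s, loss0, src),
               "dt <= 100")
})

test_that("interior mass budget closes exactly each step", {
  loss <- loss_params(1.3e-5, 1.6e-6)
  k <- loss$k_p + loss$k_b
  set.seed(3)
  c <- runif(grid_s$n)
  v <- 0.3; dt <- 120
  out <- tracer_step(c, v, dt, grid_s, loss, src)
  m_new <- sum(out[2:grid_s$n])
  m_pred <- exp(-k * dt) *
    (sum(c[2:grid_s$n]) - v * dt / grid_s$dy * (c[grid_s$n] - c[1]))
  expect_equal(m_new, m_pred, tolerance = 1e-14)
})

test_that("run matches the analytic steady-state profile", {
  g <- grid_1d(y_max = 29000, dy = 50)
  loss <- loss_params(1.3e-5, 1.6e-6)
  v <- 0.1
  nh <- ceiling(3 * 29000 / v / 3600)
  tf <- run_transport(const_velocity(v, nh), g, loss, src, dt = 100)
  got <- tf$c[length(tf$time), ]
  want <- steady_state_analytic(v, loss, src, g)
  rel_l2 <- sqrt(sum((got - want)^2) / sum(want^2))
  expect_lt(rel_l2, 0.01)
  expect_equal(got[1], src$c0)   # Dirichlet boundary held at the source
})

test_that("steady-state error converges at first order in dy", {
  loss <- loss_params(1.3e-5, 1.6e-6)
  v <- 0.1
  nh <- ceiling(3 * 29000 / v / 3600)
  err <- vapply(c(200, 100, 50), function(dy) {
    g <- grid_1d(29000, dy)
    tf <- run_transport(const_velocity(v, nh), g, loss, src, dt = 100)
    want <- steady_state_analytic(v, loss, src, g)
    sqrt(sum((tf$c[length(tf$time), ] - want)^2) / sum(want^2))
  }, 0)
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 1.5 & ratios < 3))
})

test_that("stagnant flow leaves the domain empty beyond the boundary", {
  g <- grid_1d(5000, 100)
  tf <- run_transport(const_velocity(0, 48), g, loss_params(), src)
  expect_true(all(tf$c[, -1] == 0))
})

test_that("uniform and varying modes agree for alongshore-constant velocity", {
  g <- grid_1d(8000, 200)
  set.seed(5)
  n <- 72
  v <- 0.3 * sin(2 * pi * (1:n) / 36) + rnorm(n, 0, 0.05)
  tm <- hours(n)
  u <- run_transport(as_velocity_series(tm, v), g, loss_params(), src,
                     dt = 300)
  vv <- run_transport(
    velocity_series_varying(tm, g$y, matrix(v, n, g$n)),
    g, loss_params(), src, dt = 300)
  expect_equal(u$c, vv$c, tolerance = 1e-13)
})

test_that("concentrations stay within [0, c0] under reversing forcing", {
  g <- grid_1d(8000, 200)
  set.seed(9)
  n <- 240
  v <- 0.5 * sin(2 * pi * (1:n) / 48) + rnorm(n, 0, 0.1)
  tf <- run_transport(as_velocity_series(hours(n), v), g,
                      loss_params(), source_config(c0 = 0.4), dt = 200)
  expect_gte(min(tf$c), 0)
  expect_lte(max(tf$c), 0.4 + 1e-12)
})

test_that("solution is linear in the boundary concentration", {
  g <- grid_1d(8000, 200)
  set.seed(13)
  n <- 96
  v <- abs(0.3 * sin(2 * pi * (1:n) / 40)) + 0.02
  vel <- as_velocity_series(hours(n), v)
  a <- run_transport(vel, g, loss_params(), source_config(c0 = 0.1), dt = 300)
  b <- run_transport(vel, g, loss_params(), source_config(c0 = 0.3), dt = 300)
  expect_equal(3 * a$c, b$c, tolerance = 1e-12)
})

test_that("analytic profile: source value, lossless limit, domain errors", {
  g <- grid_1d(10000, 100)
  loss <- loss_params(1.3e-5, 1.6e-6)
  p <- steady_state_analytic(0.1, loss, src, g)
  expect_equal(p[1], src$c0)
  expect_equal(p[g$y == 10000], src$c0 * exp(-1.46), tolerance = 1e-12)
  expect_equal(steady_state_analytic(0.1, loss_params(0, 0), src, g),
               rep(src$c0, g$n))
  expect_error(steady_state_analytic(-0.1, loss, src, g), "positive")
  expect_error(steady_state_analytic(0, loss, src, g), "positive")
})

test_that("forcing gaps and CFL violations abort a run", {
  g <- grid_1d(5000, 100)
  tm <- hours(48); tm[25:48] <- tm[25:48] + 12 * 3600
  expect_error(run_transport(as_velocity_series(tm, rep(0.1, 48)), g,
                             loss_params(), src), "gap")
  expect_error(run_transport(const_velocity(1.2, 24), g, loss_params(), src,
                             dt = 120), "CFL")
})
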