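test_that("homing angle is the signed rotation onto the nest direction", {
  expect_equal(homing_angle(c(10, 0), pi, c(0, 0)), 0)
  expect_equal(homing_angle(c(10, 0), 0, c(0, 0)), pi)   # boundary of (-pi, pi]
  expect_equal(homing_angle(c(0, -10), 0, c(0, 0)), pi / 2)
  expect_error(homing_angle(c(0, 0), 0, c(0, 0)), "coincides")
})

test_that("target angular speed is zero while exploring, eta* phi while returning", {
  p <- default_params()
  exploring <- bee_state(c(50, 20), heading = 1, switch_time = Inf)
  expect_equal(target_angular_speed(exploring, p), 0)
  returning <- bee_state(c(10, 0), heading = 0, switch_time = 0, clock = 1)
  expect_equal(target_angular_speed(returning, p), 0.2 * pi)
  aligned <- bee_state(c(10, 0), heading = pi, switch_time = 0, clock = 1)
  expect_equal(target_angular_speed(aligned, p), 0)
})

test_that("the OU step matches its closed form and transition variance", {
  p <- default_params()
  expect_equal(ou_update(0, 0, p, 0), 0)
  expect_equal(ou_update(1, 0, p, 0), exp(-0.01))
  # analytic transition variance vs a large sample
  s2 <- p$sigma^2 * (1 - exp(-2 * p$gamma * p$dt)) / (2 * p$gamma)
  set.seed(101)
  draws <- ou_update(0, 0, p, rnorm(1e6))
  expect_equal(var(draws), s2, tolerance = 3 * sqrt(2 / 1e6))
  # mean reversion pulls toward the target
  expect_equal(ou_update(0, 1, p, 0), 1 - exp(-0.01))
})

test_that("switching times are exponential with mean alpha", {
  p <- default_params()
  set.seed(102)
  draws <- draw_switch_time(p, 1e5)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 30, tolerance = 0.3 / 30)
  expect_equal(mean(draws <= 30), 1 - exp(-1), tolerance = 0.01)
})

test_that("noise-free dynamics are ballistic, circular, and speed-preserving", {
  # sigma = 0, omega = 0: straight flight at constant speed
  p0 <- model_params(sigma = 0, alpha = 1e9, eta_star = 0)
  st <- bee_state(c(0, 0), heading = pi / 6)
  for (i in 1:100) st <- advance_state(st, p0, noise = 0)
  expect_equal(st$position,
               100 * p0$speed * p0$dt * c(cos(pi / 6), sin(pi / 6)),
               tolerance = 1e-9)

  # near-zero relaxation keeps omega = c: circle of radius v / |c|
  pc <- model_params(gamma = 1e-9, sigma = 0, alpha = 1e9, eta_star = 0)
  cc <- 0.5
  st <- bee_state(c(0, 0), heading = 0, angular_speed = cc)
  radius <- pc$speed / cc
  centre <- c(0, radius)   # left of the initial heading (ccw turn)
  devs <- prev <- c(0, 0)
  for (i in 1:500) {
    st <- advance_state(st, pc, noise = 0)
    expect_equal(sqrt(sum((st$position - prev)^2)), pc$speed * pc$dt,
                 tolerance = 1e-9)
    prev <- st$position
    devs <- c(devs, abs(sqrt(sum((st$position - centre)^2)) - radius))
  }
  expect_lt(max(devs), pc$speed * pc$dt)
})

test_that("the compiled engine reproduces the R reference step for step", {
  p <- default_params()
  set.seed(103)
  ref <- r_reference_path(p, 200)
  set.seed(103)
  loop <- simulate_loop(p)
  expect_gte(n_samples(loop), 201)   # loop still running after 2 s
  expect_equal(loop$x[1:201], ref[, 1], tolerance = 1e-10)
  expect_equal(loop$y[1:201], ref[, 2], tolerance = 1e-10)
})

test_that("loops start at the nest, end inside the nest disc, after tau", {
  p <- default_params()
  set.seed(104)
  loops <- replicate(300, simulate_loop(p), simplify = FALSE)
  terminated <- !vapply(loops, function(l) l$censored, logical(1))
  expect_gte(mean(terminated), 0.99)
  for (l in loops[terminated][1:50]) {
    expect_equal(c(l$x[1], l$y[1]), c(0, 0))
    d_end <- sqrt(l$x[n_samples(l)]^2 + l$y[n_samples(l)]^2)
    expect_lte(d_end, p$nest_radius)
    expect_gte(max(l$t), l$switch_time)
  }
})

test_that("speed is conserved exactly along a recorded trip", {
  p <- default_params()
  set.seed(105)
  tr <- simulate_trip(p, duration = 30)
  expect_equal(n_samples(tr), 3001)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(max(abs(steps - p$speed * p$dt)), 0, tolerance = 1e-9)
})

test_that("a 900 s trip records duration/dt + 1 states and logs its loops", {
  p <- default_params()
  set.seed(106)
  tr <- simulate_trip(p, duration = 900)
  expect_equal(n_samples(tr), 90001)
  expect_gt(length(tr$loop_entries), 0)
  # at every logged nest entry the bee is inside the nest disc
  idx <- match(round(tr$loop_entries, 6), round(tr$t, 6))
  d <- sqrt(tr$x[idx]^2 + tr$y[idx]^2)
  expect_true(all(d <= p$nest_radius))
})

test_that("noise-free trajectories are rotationally symmetric", {
  p <- model_params(sigma = 0)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  delta <- 0.73
  # return phase from the start: homing from a rotated start with rotated
  # heading must give the rotated path
  s1 <- bee_state(c(80, 30), heading = 1.1, switch_time = 0, clock = 1)
  s2 <- bee_state(rot(c(80, 30), delta), heading = 1.1 + delta,
                  switch_time = 0, clock = 1)
  for (i in 1:400) {
    s1 <- advance_state(s1, p, noise = 0)
    s2 <- advance_state(s2, p, noise = 0)
    expect_equal(s2$position, rot(s1$position, delta), tolerance = 1e-9)
  }
})

test_that("halving dt leaves the loop-extension distribution unchanged", {
  # the OU transition is exact for any step, so only the phase-switch and
  # termination discretization change; distributions must agree within noise
  p1 <- default_params()
  p2 <- model_params(dt = 0.005)
  set.seed(107)
  e1 <- vapply(replicate(300, simulate_loop(p1, record_interval = 0.1),
                         simplify = FALSE), loop_extension, numeric(1))
  e2 <- vapply(replicate(300, simulate_loop(p2, record_interval = 0.1),
                         simplify = FALSE), loop_extension, numeric(1))
  expect_gt(suppressWarnings(ks.test(e1, e2)$p.value), 0.01)
})

test_that("pure-exploration angular speed attains the stationary variance", {
  p <- default_params()
  set.seed(108)
  om <- simulate_angular_speed(4e5, p, burn_in = 1e4)
  target <- p$sigma^2 / (2 * p$gamma)
  a <- exp(-p$gamma * p$dt)
  n_eff <- length(om) * (1 - a) / (1 + a)
  expect_equal(var(om), target, tolerance = 3 * sqrt(2 / n_eff))
})
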