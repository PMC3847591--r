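test_that("muscle torque follows pennation and moment arm", {
  z <- const_series(0, n = 10)
  expect_equal(muscle_torque(z, 0.2, 0.05)$values, rep(0, 10))
  f <- const_series(100, n = 4)
  expect_equal(muscle_torque(f, 0, 0.05)$values, rep(5, 4))
  gas <- const_series(1600, n = 2)
  tq <- muscle_torque(gas, 14 * pi / 180, 0.0515)
  expect_equal(tq$values[1], 1600 * cos(14 * pi / 180) * 0.0515)
  expect_equal(tq$values[1], 79.95, tolerance = 0.01)
})

test_that("contribution ratios reproduce the printed GAS/SOL split", {
  cfg <- joint_config()
  r <- contribution_ratio(cfg)
  expect_equal(sum(r), 1)
  expect_equal(round(unname(r), 2), c(0.41, 0.59))

  twin <- joint_config(
    muscles = list(A = gas_params(), B = gas_params()),
    moment_arm = c(A = 0.05, B = 0.05)
  )
  expect_equal(unname(contribution_ratio(twin)), c(0.5, 0.5))
  solo <- joint_config(muscles = list(A = gas_params()),
                       moment_arm = c(A = 0.05))
  expect_error(contribution_ratio(solo), "two muscles")
})

test_that("normalized summed torque scales linearly and self-normalizes", {
  cfg <- joint_config(mvc_torque = 100)
  t1 <- const_series(30, n = 8)
  t2 <- const_series(20, n = 8)
  out <- normalized_sum_torque(list(t1, t2), cfg)
  expect_equal(out$values, rep(0.5, 8))
  # scaling both inputs by c scales the output by c
  out3 <- normalized_sum_torque(
    list(const_series(90, n = 8), const_series(60, n = 8)), cfg
  )
  expect_equal(out3$values, 3 * out$values)
  # an MVC trial maps to peak 1 when normalized by its own peak
  mvc_sum <- uniform_series(c(10, 80, 50), dt = 0.1)
  cfg2 <- joint_config(mvc_torque = max(mvc_sum$values))
  expect_equal(max(normalized_sum_torque(list(mvc_sum), cfg2)$values), 1)
  expect_error(normalized_sum_torque(list(t1), joint_config()), "mvc_torque")
})

test_that("error metrics match hand arithmetic", {
  a <- uniform_series(c(0, 0.2), dt = 1)
  b <- uniform_series(c(0.1, 0.1), dt = 1)
  expect_equal(rms_error(a, b), 0.1)
  expect_equal(rms_error(a, a), 0)
  off <- uniform_series(a$values + 0.1, dt = 1)
  expect_equal(rms_error(off, a), 0.1)

  est <- uniform_series(c(0, 0.5, 0.1), dt = 1)
  meas <- uniform_series(c(0.7, 0.1, 0), dt = 1)
  expect_equal(peak_error(est, meas, 1:3), 0.2)
  expect_equal(peak_error(est, est, 1:3), 0)
  # insensitive to alignment: same peaks, shifted position
  sh <- uniform_series(c(0.5, 0, 0.1), dt = 1)
  expect_equal(peak_error(sh, meas, 1:3), 0.2)
  expect_error(rms_error(a, b, integer(0)), "window")
  expect_error(peak_error(a, b, 5:6), "window")
})

test_that("shape-factor calibration recovers the generating value", {
  p <- uniform_series(seq(0, 1, length.out = 200), dt = 0.01)
  runner <- function(A) muscle_activation(p, A)
  measured <- runner(-1.5)
  A_hat <- calibrate_shape_factor(measured, runner)
  expect_equal(A_hat, -1.5, tolerance = 0.05)
  # objective at the optimum beats a 20-point grid
  obj <- function(A) rms_error(runner(A), measured)
  grid <- seq(-3, -0.01, length.out = 20)
  expect_true(all(obj(A_hat) <= sapply(grid, obj) + 1e-12))
  # boundary optimum is returned exactly
  measured3 <- runner(-3)
  expect_equal(calibrate_shape_factor(measured3, runner), -3)
})
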