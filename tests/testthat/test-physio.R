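test_that("chemical input follows the switched-rate definition", {
  # zero EMG: Pi_c = 0 everywhere, u = Ur
  z <- const_series(0, n = 2048, dt = 1 / 2048)
  expect_warning(
    drive <- make_chemical_input(z, envelope_config(), threshold = 0.5),
    "threshold exceeds"
  )
  expect_equal(drive$pi_c$values, rep(0, 2048))
  expect_equal(drive$u$values, rep(10, 2048))

  # envelope everywhere above threshold: Pi_c = 1, u = Uc
  set.seed(3)
  loud <- uniform_series(rnorm(4096), dt = 1 / 2048)
  drive2 <- make_chemical_input(loud, envelope_config(), threshold = 1e-6)
  expect_true(all(drive2$pi_c$values == 1))
  expect_equal(drive2$u$values, rep(5, 4096))
  expect_error(make_chemical_input(loud, envelope_config(), threshold = 0),
               "> 0")
})

test_that("indicator transitions match threshold crossings of the envelope", {
  fs <- 2048
  t <- seq(0, 3, by = 1 / fs)
  carrier <- sin(2 * pi * 120 * t)
  window <- as.numeric(t > 1 & t < 2)
  raw <- uniform_series(carrier * window, dt = 1 / fs)
  drive <- make_chemical_input(raw, envelope_config(), threshold = 0.2)
  # index-scan oracle on the returned 30 Hz envelope
  expected <- as.numeric(drive$envelope$values > 0.2)
  expect_equal(drive$pi_c$values, expected)
  # and the burst interval sits close to the commanded window
  on <- range(which(drive$pi_c$values == 1))
  expect_equal(on[1] / fs, 1, tolerance = 0.05)
  expect_equal(on[2] / fs, 2, tolerance = 0.05)

  # electromechanical delay shifts the indicator by whole samples
  d <- 0.04
  delayed <- make_chemical_input(raw, envelope_config(), threshold = 0.2,
                                 delay_s = d)
  shift <- round(d * fs)
  expect_equal(delayed$pi_c$values[-(1:shift)],
               drive$pi_c$values[seq_len(length(t) - shift)])
})

test_that("recruitment modes implement their hold conventions", {
  n <- 100
  dt <- 0.01
  pi_c <- uniform_series(rep(c(0, 1, 0, 1, 0), each = 20), dt = dt)
  pconst <- const_series(0.4, n = n, dt = dt)
  for (m in c("continuous", "hold_at_onset", "hold_phase_max")) {
    expect_equal(recruitment_alpha(pconst, pi_c, m)$values, rep(0.4, n))
  }
  ramp <- uniform_series(seq(0, 1, length.out = n), dt = dt)
  a_max <- recruitment_alpha(ramp, pi_c, "hold_phase_max")
  a_on <- recruitment_alpha(ramp, pi_c, "hold_at_onset")
  # index-scan oracle over the contraction runs
  runs <- list(21:40, 61:80)
  for (idx in runs) {
    expect_equal(a_max$values[idx], rep(max(ramp$values[idx]), 20))
    expect_equal(a_on$values[idx], rep(ramp$values[idx[1]], 20))
  }
  out <- setdiff(seq_len(n), unlist(runs))
  expect_equal(a_on$values[out], ramp$values[out])
  expect_error(
    recruitment_alpha(const_series(0.2, n = 5, dt = dt), pi_c),
    "length"
  )
})

test_that("contraction onset signs and relaxation closed form hold", {
  pp <- physio_params(gas_params())
  d0 <- physio_rhs(c(0, 0, 0), u_t = 5, pi_c_t = 1, alpha_t = 0.5,
                   mt_velocity = 0, params = pp)
  expect_gt(d0[1], 0) # stiffness builds
  expect_gt(d0[2], 0) # force builds
  expect_lt(d0[3], 0) # CE starts shortening

  # relaxation in the rigid-tendon limit: pure exponential decay at Ur
  pp_rigid <- physio_params(gas_params(kt = 1.8e5 * 1e4))
  st <- c(2000, 400, 0)
  d1 <- physio_rhs(st, u_t = 10, pi_c_t = 0, alpha_t = 0.7,
                   mt_velocity = 0, params = pp_rigid)
  expect_equal(d1[2], -10 * st[2], tolerance = 1e-3 * 10 * st[2])
  expect_equal(d1[1], -10 * st[1], tolerance = 1e-3 * 10 * st[1])
})

test_that("strain-rate sign equals the sign of its numerator", {
  pp <- physio_params(sol_params())
  set.seed(99)
  n_cases <- 10000
  kc <- runif(n_cases, 0, 2 * pp$km0)
  Fc <- runif(n_cases, 0, pp$Fm)
  eps <- runif(n_cases, -0.2, 0.2)
  u <- ifelse(runif(n_cases) < 0.5, 5, 10)
  pic <- as.numeric(u == 5)
  alpha <- runif(n_cases)
  ok <- TRUE
  for (i in seq_len(n_cases)) {
    st <- c(kc[i], Fc[i], eps[i])
    num <- Fc[i] * u[i] -
      alpha[i] * pp$Fm * force_length(eps[i], pp$b) * pic[i] * pp$Uc
    d <- physio_rhs(st, u[i], pic[i], alpha[i], 0, pp)
    if (sign(d[3]) != sign(num)) ok <- FALSE
  }
  expect_true(ok)
})

test_that("the series-elastic consistency condition is enforced", {
  pp <- physio_params(gas_params())
  bad_Fc <- pp$kt * pp$Lc0 / cos(pp$phi) + 10 * pp$Lc0 + 1
  expect_error(
    physio_rhs(c(10, bad_Fc, 0), 5, 1, 0.5, 0, pp),
    "consistency"
  )
})

test_that("simulation reproduces the rigid-tendon closed forms", {
  dt <- 1e-3
  pi_c <- uniform_series(rep(c(1, 0), each = 1000), dt = dt)
  drive <- chemical_drive_from_indicator(pi_c, Uc = 5, Ur = 10)
  pp <- physio_params(gas_params(kt = 1.8e5 * 1000))

  zero <- simulate_physio(drive, 0, pp, dt_int = dt)
  expect_equal(max(abs(zero$Fc$values)), 0)
  expect_equal(max(abs(zero$kc$values)), 0)

  tr <- simulate_physio(drive, 0.6, pp, dt_int = dt)
  tk <- (1:2000) * dt # trace k holds the state at the end of sample k
  rise <- 0.6 * pp$Fm * (1 - exp(-5 * tk[1:1000]))
  expect_lt(max(abs(tr$Fc$values[1:1000] - rise)) / (0.6 * pp$Fm), 0.005)
  decay <- tr$Fc$values[1000] * exp(-10 * (tk[1001:2000] - tk[1000]))
  expect_lt(max(abs(tr$Fc$values[1001:2000] - decay)) / (0.6 * pp$Fm), 0.005)
  # steady-state recruitment linearity in the same limit
  tr2 <- simulate_physio(drive, 0.3, pp, dt_int = dt)
  expect_equal(tr2$Fc$values[1000] / tr$Fc$values[1000], 0.5,
               tolerance = 1e-5)
})

test_that("isotonic relation matches landmarks and clamped steady states", {
  pp <- physio_params(gas_params(b = 1e6)) # optimal length throughout
  kc0 <- 0.5 * pp$km0
  iso0 <- isotonic_force_velocity(pp, kc0, 0.8, 0)
  expect_equal(iso0$force, 0.8 * pp$Fm) # isometric limit
  grid <- seq(-0.05, -2, length.out = 8)
  iso <- isotonic_force_velocity(pp, kc0, 0.8, grid)
  expect_true(all(diff(iso$force[order(iso$velocity)]) > 0)) # monotone
  expect_error(isotonic_force_velocity(pp, kc0, 0.8, 0.1), "concentric")

  # dynamic consistency at two clamped velocities
  dt <- 1e-3
  drive <- chemical_drive_from_indicator(
    uniform_series(rep(1, 3000), dt = dt), Uc = 5, Ur = 10
  )
  for (v in c(-0.3, -1.5)) {
    tr <- simulate_physio(drive, 0.8, pp, dt_int = dt, eps_c_dot = v)
    kc_ss <- tr$kc$values[3000]
    F_ss <- tr$Fc$values[3000]
    F_alg <- isotonic_force_velocity(pp, kc_ss, 0.8, v)$force
    expect_equal(F_alg, F_ss, tolerance = 0.01 * F_ss)
  }
})
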