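test_that("activation parameters enforce stability and gain constraints", {
  p <- activation_params(C1 = -0.5, C2 = -0.5)
  expect_equal(p$beta1, -1)
  expect_equal(p$beta2, 0.25)
  expect_equal(p$gamma - p$beta1 - p$beta2, 1) # unit DC gain
  expect_error(activation_params(C1 = 1.2), "stability")
  expect_error(activation_params(A = -4), "A")
  expect_error(activation_params(A = 0.5), "A")
})

test_that("zero input gives zero activation and steps converge to DC", {
  par <- activation_params()
  z <- const_series(0, n = 100)
  expect_equal(neural_activation(z, par)$values, rep(0, 100))

  step <- const_series(1, n = 3000, dt = 1 / 500)
  p <- neural_activation(step, par)
  expect_equal(p$values[3000], 1, tolerance = 1e-6)
  # intermediate DC level too
  step2 <- const_series(0.4, n = 3000, dt = 1 / 500)
  expect_equal(neural_activation(step2, par)$values[3000], 0.4,
               tolerance = 1e-6)
})

test_that("impulse response matches the double-pole closed form", {
  par <- activation_params(C1 = -0.5, C2 = -0.5, d_s = 0)
  imp <- uniform_series(c(1, rep(0, 19)), dt = 0.01)
  p <- neural_activation(imp, par)
  k <- 0:5
  expect_equal(p$values[k + 1], par$gamma * (k + 1) * 0.5^k,
               tolerance = 1e-12)
})

test_that("the delay shifts the response by whole samples", {
  dt <- 0.01
  par <- activation_params(d_s = 5 * dt)
  imp <- uniform_series(c(1, rep(0, 29)), dt = dt)
  p <- neural_activation(imp, par)
  expect_equal(p$values[1:5], rep(0, 5))
  expect_gt(p$values[6], 0)
})

test_that("neural activation is linear in its input", {
  par <- activation_params()
  set.seed(1)
  e1 <- uniform_series(runif(200, 0, 0.5), dt = 0.005)
  e2 <- uniform_series(runif(200, 0, 0.5), dt = 0.005)
  sum12 <- uniform_series(e1$values + e2$values, dt = 0.005)
  expect_equal(
    neural_activation(sum12, par)$values,
    neural_activation(e1, par)$values + neural_activation(e2, par)$values,
    tolerance = 1e-12
  )
})

test_that("nonlinear shaping fixes endpoints and matches hand evaluation", {
  p <- uniform_series(c(0, 0.5, 1), dt = 0.1)
  a <- muscle_activation(p, -1.7)
  expect_equal(a$values[1], 0)
  expect_equal(a$values[3], 1)
  expect_equal(a$values[2], (exp(-1.7 * 0.5) - 1) / (exp(-1.7) - 1))
  expect_equal(a$values[2], 0.7005, tolerance = 1e-4)
  expect_error(muscle_activation(uniform_series(c(0, 1.5), dt = 1), -1),
               "\\[0, 1\\]")
})

test_that("A -> 0 recovers the identity and A < 0 amplifies low levels", {
  p <- uniform_series(seq(0, 1, by = 0.05), dt = 0.1)
  near <- muscle_activation(p, -1e-6)
  expect_lt(max(abs(near$values - p$values)), 1e-5)
  exact <- muscle_activation(p, 0)
  expect_equal(exact$values, p$values)
  for (A in c(-0.5, -1.7, -3)) {
    a <- muscle_activation(p, A)
    inner <- p$values > 0 & p$values < 1
    expect_true(all(a$values[inner] > p$values[inner]))
    expect_true(all(diff(a$values) > 0)) # monotone
    expect_true(all(a$values >= 0 & a$values <= 1))
  }
})
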