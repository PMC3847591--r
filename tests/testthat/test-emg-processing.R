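test_that("low-pass preserves DC and high-pass removes it", {
  x <- const_series(3.7)
  lp <- zero_lag_butterworth(x, 10, 2, "low")
  hp <- zero_lag_butterworth(x, 10, 2, "high")
  expect_equal(lp$values, x$values, tolerance = 1e-10)
  expect_lt(max(abs(hp$values)), 1e-10)
})

test_that("zero-lag filtering has exactly zero phase on a symmetric pulse", {
  t <- seq(-2, 2, by = 1 / 256)
  x <- uniform_series(exp(-t^2 / (2 * 0.05^2)), dt = 1 / 256)
  for (cutoff in c(5, 20)) {
    y <- zero_lag_butterworth(x, cutoff, 4, "low")
    expect_identical(which.max(y$values), which.max(x$values))
  }
})

test_that("attenuation at the cutoff matches the coefficient-level response", {
  fs <- 256
  cutoff <- 10
  x <- sine_series(cutoff, fs = fs, duration = 8)
  y <- zero_lag_butterworth(x, cutoff, 4, "low")
  # independent oracle: |H|^2 from the order-2 design coefficients
  bf <- signal::butter(2, W = cutoff / (fs / 2), type = "low")
  expected <- Mod(arma_response(bf, cutoff, fs))^2
  expect_equal(expected, 0.5, tolerance = 1e-6) # squared -3 dB point
  expect_equal(central_amplitude(y), expected, tolerance = 0.01)

  # single-direction switch: order-4 single pass, -3 dB at the cutoff
  y1 <- zero_lag_butterworth(x, cutoff, 4, "low", zero_lag = FALSE)
  bf4 <- signal::butter(4, W = cutoff / (fs / 2), type = "low")
  expect_equal(central_amplitude(y1), Mod(arma_response(bf4, cutoff, fs)),
               tolerance = 0.01)
})

test_that("filter parameter errors are raised", {
  x <- const_series(1, n = 100)
  expect_error(zero_lag_butterworth(x, 200, 4, "low"), "Nyquist")
  expect_error(zero_lag_butterworth(x, -1, 4, "low"), "Nyquist")
  expect_error(zero_lag_butterworth(x, 10, 3, "low"), "even")
  short <- uniform_series(rep(1, 8), dt = 1 / 256)
  expect_error(zero_lag_butterworth(short, 10, 4, "low"), "too short")
})

test_that("rectification is |x| and idempotent on nonnegatives", {
  x <- uniform_series(c(-1, 2, -3), dt = 0.1)
  expect_equal(rectify(x)$values, c(1, 2, 3))
  z <- uniform_series(rep(0, 5), dt = 0.1)
  expect_equal(rectify(z)$values, rep(0, 5))
  expect_equal(rectify(rectify(x))$values, rectify(x)$values)
})

test_that("moving-average envelope follows its definition", {
  cfg <- envelope_config(mav_window = 5 / 256)
  # constants are preserved by both envelope variants
  cc <- const_series(0.8)
  expect_equal(emg_envelope(cc, cfg)$values, cc$values)
  expect_equal(emg_envelope(cc, envelope_config())$values, cc$values,
               tolerance = 1e-9)
  # unit impulse -> plateau of 1/w over the window
  imp <- uniform_series(c(rep(0, 20), 1, rep(0, 20)), dt = 1 / 256)
  env <- emg_envelope(imp, cfg)
  expect_equal(max(env$values), 1 / 5)
  expect_equal(sum(env$values > 1 / 5 - 1e-12), 5L)
  # window below one sample errors
  expect_error(
    emg_envelope(imp, envelope_config(mav_window = 1e-4)),
    "shorter than one sample"
  )
  expect_error(emg_envelope(uniform_series(c(-1, 1), dt = 0.1), cfg),
               "nonnegative")
})

test_that("low-pass envelope of rectified sinusoid gives its mean 2/pi", {
  x <- rectify(sine_series(50, fs = 1000, duration = 6))
  env <- emg_envelope(x, envelope_config(lp_cutoff = 2))
  n <- length(env$values)
  mid <- env$values[seq(round(n / 3), round(2 * n / 3))]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.02)
  expect_lt(max(abs(mid - 2 / pi)) / (2 / pi), 0.02)
})

test_that("MVC normalization scales correctly and composes", {
  x <- uniform_series(c(0, 2, 4), dt = 0.1)
  expect_equal(normalize_mvc(x, 4)$values, c(0, 0.5, 1))
  expect_error(normalize_mvc(x, 0), "positive")
  expect_error(normalize_mvc(x, -2), "positive")
  twice <- normalize_mvc(normalize_mvc(x, 2), 3)
  once <- normalize_mvc(x, 6)
  expect_equal(twice$values, once$values)
})

test_that("an MVC envelope normalized by its own peak has maximum 1", {
  set.seed(42)
  raw <- uniform_series(rnorm(2048), dt = 1 / 1024)
  cfg <- envelope_config()
  env <- process_emg(raw, cfg)
  cfg$mvc_peak <- max(env$values)
  expect_equal(max(process_emg(raw, cfg)$values), 1)
})

test_that("the conditioning chain commutes with positive amplitude scaling", {
  set.seed(7)
  raw <- uniform_series(rnorm(1024), dt = 1 / 512)
  cfg <- envelope_config()
  e1 <- process_emg(raw, cfg)
  e2 <- process_emg(uniform_series(3 * raw$values, raw$dt), cfg)
  expect_equal(e2$values, 3 * e1$values, tolerance = 1e-10)
})

test_that("envelope config rejects inconsistent cutoffs", {
  expect_error(envelope_config(lp_cutoff = 40, hp_cutoff = 30), "lp_cutoff")
  expect_error(envelope_config(mvc_peak = -1), "mvc_peak")
})
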