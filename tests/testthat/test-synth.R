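test_that("command profiles stay in range and carry labels", {
  prof <- build_command(segments_random(3), 512)
  expect_true(all(prof$command$values >= 0 & prof$command$values <= 1))
  expect_equal(length(prof$labels), length(prof$command))
  expect_setequal(unique(prof$labels), c("rest", "fast_short", "slow_long"))
  expect_error(
    build_command(data.frame(label = "x", duration = 1, level = 1.2), 512),
    "\\[0, 1\\]"
  )
})

test_that("a silent noise-free command produces a silent channel", {
  cfg <- synth_trial_config(fs = 512, noise_rms = 0, seed = 5)
  cmd <- const_series(0, n = 512, dt = 1 / 512)
  emg <- generate_surface_emg(cmd, cfg)
  expect_equal(max(abs(emg$values)), 0)
})

test_that("generation is deterministic per seed", {
  cfg <- synth_trial_config(fs = 512, seed = 11)
  cmd <- build_command(segments_plateau(0.5), 512)$command
  e1 <- generate_surface_emg(cmd, cfg)
  e2 <- generate_surface_emg(cmd, cfg)
  expect_identical(e1$values, e2$values)
  e3 <- generate_surface_emg(cmd, cfg, seed = 12)
  expect_false(identical(e1$values, e3$values))
})

test_that("the processed envelope tracks the command amplitude", {
  # interference-model scaling: the 2 Hz envelope of a 70 % plateau is
  # about 0.7 times the MVC-plateau envelope, and doubling the command
  # about doubles the envelope
  fs <- 2048
  cfg <- synth_trial_config(seed = 7)
  mid_env <- function(level) {
    cmd <- build_command(segments_plateau(level), fs)$command
    e <- process_emg(generate_surface_emg(cmd, cfg), envelope_config())
    n <- length(e)
    mean(e$values[round(n * 0.45):round(n * 0.6)])
  }
  e35 <- mid_env(0.35)
  e70 <- mid_env(0.70)
  e100 <- mid_env(1.0)
  expect_equal(e70 / e100, 0.7, tolerance = 0.10)
  expect_equal(e70 / e35, 2, tolerance = 0.15)
})

test_that("reference trials give zero torque for a zero command", {
  fs <- 512
  cfg <- synth_trial_config(fs = fs, noise_rms = 0, seed = 2)
  prof <- list(command = const_series(0, n = fs, dt = 1 / fs),
               labels = rep("rest", fs))
  for (m in c("hill_linear", "physio")) {
    trial <- generate_reference_trial(prof, cfg, m)
    expect_equal(max(abs(trial$torque$values)), 0)
  }
})

test_that("a rigid-tendon plateau reaches the closed-form torque", {
  fs <- 512
  joint <- joint_config(
    muscles = list(GAS = gas_params(kt = 1.8e5 * 1000),
                   SOL = sol_params(kt = 1.8e5 * 1000))
  )
  segs <- data.frame(label = c("rest", "hold"), duration = c(0.2, 3),
                     level = c(0, 0.6), ramp = c(0, 0.1))
  cmd <- build_command(segs, fs)$command
  tq <- forward_torque(cmd, "physio", joint)
  expected <- 0.6 * sum(sapply(names(joint$muscles), function(nm) {
    m <- joint$muscles[[nm]]
    m$Fm * cos(m$phi) * joint$moment_arm[[nm]]
  }))
  expect_equal(max(tq$values), expected, tolerance = 0.01 * expected)
})

test_that("short bursts lose force in the physio model but not in Hill", {
  short_cmd <- burst_command(0.2, fs = 512)
  long_cmd <- burst_command(2.0, fs = 512)
  peak <- function(cmd, m) max(forward_torque(cmd, m)$values)
  ratio_physio <- peak(short_cmd, "physio") / peak(long_cmd, "physio")
  ratio_hill <- peak(short_cmd, "hill_linear") / peak(long_cmd, "hill_linear")
  expect_lt(ratio_physio, 0.8)
  expect_gt(ratio_hill, 0.9)
})
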