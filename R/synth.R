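#' Synthetic-trial configuration
#'
#' Settings of the motor-unit-based surface-EMG simulator. The simulated
#' channel is the interference pattern of `n_motor_units` motor-unit
#' action-potential trains: unit `i` has a recruitment threshold
#' `theta_i = (i - 0.5) / n` spread over (0, 1), fires once the command
#' exceeds its threshold, at a renewal rate that rises linearly with the
#' command above threshold (`fmin + (fmax - fmin) * (x - theta_i)`, capped
#' at `fmax`), with a 15 percent inter-spike-interval coefficient of
#' variation. Each firing adds a biphasic zero-mean waveform (first
#' derivative of a Gaussian). Following the size principle, the waveform
#' amplitude of unit `i` grows with its threshold as `theta_i^0.25`; the
#' mild quarter-power law is calibrated so that the 2 Hz rectified
#' envelope of the summed train tracks the command approximately linearly
#' (a 50-unit pool stands in for a much larger physiological one, and the
#' sparse low-level interference otherwise under-reads the mean absolute
#' value), which is what the downstream MVC-normalized pipeline assumes of
#' real EMG.
#'
#' @param fs Sampling rate in Hz (default 2048, the acquisition rate the
#'   package targets).
#' @param n_motor_units Number of motor units (default 50).
#' @param firing_rate_range Minimum and maximum firing rates in Hz
#'   (default 8 and 35).
#' @param ap_duration Duration of the biphasic waveform in seconds
#'   (default 8 ms).
#' @param noise_rms Additive Gaussian noise standard deviation as a fraction
#'   of the peak absolute interference amplitude (default 0.02).
#' @param isi_cv Coefficient of variation of the renewal inter-spike
#'   intervals (default 0.15).
#' @param seed Integer seed; all randomness of a trial flows from it.
#' @return An object of class `synth_trial_config`.
#' @export
synth_trial_config <- function(fs = 2048, n_motor_units = 50,
                               firing_rate_range = c(8, 35),
                               ap_duration = 0.008, noise_rms = 0.02,
                               isi_cv = 0.15, seed = 1L) {
  if (fs <= 2 / ap_duration) {
    stop("'fs' must exceed twice the waveform bandwidth (2 / ap_duration)")
  }
  if (n_motor_units < 1) stop("'n_motor_units' must be >= 1")
  if (length(firing_rate_range) != 2L ||
      firing_rate_range[1] <= 0 ||
      firing_rate_range[2] <= firing_rate_range[1]) {
    stop("'firing_rate_range' must be increasing and positive")
  }
  if (noise_rms < 0 || isi_cv < 0) {
    stop("'noise_rms' and 'isi_cv' must be >= 0")
  }
  structure(
    list(
      fs = fs, n_motor_units = as.integer(n_motor_units),
      firing_rate_range = firing_rate_range,
      ap_duration = ap_duration, noise_rms = noise_rms,
      isi_cv = isi_cv, seed = as.integer(seed)
    ),
    class = "synth_trial_config"
  )
}

#' Build a labelled command profile
#'
#' Turns a segment table into a piecewise activation command in `[0, 1]`
#' with per-sample labels. Each segment holds `level` for `duration`
#' seconds, preceded by a linear ramp of `ramp` seconds from the previous
#' level (the ramp carries the segment's label).
#'
#' @param segments `data.frame` with columns `label` (character), `duration`
#'   (s), `level` (in `[0, 1]`) and optionally `ramp` (s, default 0).
#' @param fs Sampling rate in Hz.
#' @return List with `command` ([uniform_series()]) and `labels` (character
#'   vector, one per sample).
#' @export
build_command <- function(segments, fs) {
  stopifnot(is.data.frame(segments),
            all(c("label", "duration", "level") %in% names(segments)))
  if (any(segments$level < 0 | segments$level > 1)) {
    stop("command levels must lie in [0, 1]")
  }
  if (is.null(segments$ramp)) segments$ramp <- 0
  dt <- 1 / fs
  vals <- numeric(0)
  labs <- character(0)
  prev <- 0
  for (i in seq_len(nrow(segments))) {
    nr <- round(segments$ramp[i] * fs)
    nh <- round(segments$duration[i] * fs)
    if (nr > 0) {
      vals <- c(vals, prev + (segments$level[i] - prev) * seq_len(nr) / nr)
      labs <- c(labs, rep(segments$label[i], nr))
    }
    vals <- c(vals, rep(segments$level[i], nh))
    labs <- c(labs, rep(segments$label[i], nh))
    prev <- segments$level[i]
  }
  list(command = uniform_series(vals, dt = dt), labels = labs)
}

#' Standard command profiles
#'
#' Ready-made segment tables emulating an isometric plantar-flexion session:
#' an MVC trial, 30 and 70 percent-of-MVC plateaus, and a random trial
#' mixing fast-short bursts with slow-long ramped contractions.
#'
#' @param level Plateau level for `segments_plateau()`.
#' @param seed Seed for the randomized burst ordering/amplitudes of
#'   `segments_random()`.
#' @return A segment `data.frame` for [build_command()].
#' @name command_profiles
NULL

#' @rdname command_profiles
#' @export
segments_mvc <- function() {
  data.frame(
    label = c("rest", "mvc", "rest"),
    duration = c(1, 3, 1.5),
    level = c(0, 1, 0),
    ramp = c(0, 0.5, 0.5)
  )
}

#' @rdname command_profiles
#' @export
segments_plateau <- function(level) {
  lab <- paste0("plateau", round(100 * level))
  data.frame(
    label = c("rest", lab, "rest"),
    duration = c(1, 3, 1.5),
    level = c(0, level, 0),
    ramp = c(0, 0.5, 0.5)
  )
}

#' @rdname command_profiles
#' @export
segments_random <- function(seed = 1L) {
  set.seed(seed)
  lvl_fast <- stats::runif(2, 0.5, 0.8)
  lvl_slow <- stats::runif(2, 0.4, 0.7)
  data.frame(
    label = c("rest", "fast_short", "rest", "slow_long", "rest",
              "fast_short", "rest", "slow_long", "rest"),
    duration = c(1, 0.25, 1.5, 2.5, 1.5, 0.25, 1.5, 2.5, 1.5),
    level = c(0, lvl_fast[1], 0, lvl_slow[1], 0,
              lvl_fast[2], 0, lvl_slow[2], 0),
    ramp = c(0, 0.05, 0.05, 0.8, 0.8, 0.05, 0.05, 0.8, 0.8)
  )
}

# Gaussian-derivative biphasic waveform, peak amplitude 1, zero mean.
biphasic_waveform <- function(ap_duration, fs) {
  sigma <- ap_duration / 6
  t <- seq(-3 * sigma, 3 * sigma, by = 1 / fs)
  w <- -t / sigma * exp(-t^2 / (2 * sigma^2))
  w / max(abs(w))
}

#' Simulate a surface-EMG channel
#'
#' Generates the motor-unit interference pattern driven by a command profile
#' in `[0, 1]`; see [synth_trial_config()] for the recruitment, rate and
#' amplitude model. All randomness flows from `seed`, so equal seeds give
#' identical signals.
#'
#' @param command Activation command in `[0, 1]` as a [uniform_series()].
#' @param cfg A [synth_trial_config()].
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return Simulated EMG as a [uniform_series()] on the command time base.
#' @export
generate_surface_emg <- function(command, cfg, seed = cfg$seed) {
  stopifnot(is_uniform_series(command), inherits(cfg, "synth_trial_config"))
  x <- command$values
  if (min(x) < 0 || max(x) > 1) stop("command must lie in [0, 1]")
  fs <- 1 / command$dt
  n <- length(x)
  t_end <- n / fs
  set.seed(seed)

  nmu <- cfg$n_motor_units
  theta <- (seq_len(nmu) - 0.5) / nmu
  amp <- theta^0.25
  fmin <- cfg$firing_rate_range[1]
  fmax <- cfg$firing_rate_range[2]
  w <- biphasic_waveform(cfg$ap_duration, fs)
  nw <- length(w)

  sig <- numeric(n + nw)
  for (i in seq_len(nmu)) {
    t <- stats::runif(1) / fmax   # random initial phase
    while (t < t_end) {
      k <- min(n, 1L + as.integer(floor(t * fs)))
      if (x[k] <= theta[i]) {
        t <- t + 0.010            # inactive: re-test 10 ms later
        next
      }
      rate <- min(fmin + (fmax - fmin) * (x[k] - theta[i]), fmax)
      isi <- max(1 / rate * (1 + cfg$isi_cv * stats::rnorm(1)), 1 / fmax / 2)
      # spike at t: add the waveform
      idx <- k:(k + nw - 1L)
      sig[idx] <- sig[idx] + amp[i] * w
      t <- t + isi
    }
  }
  sig <- sig[seq_len(n)]
  peak <- max(abs(sig))
  if (cfg$noise_rms > 0 && peak > 0) {
    sig <- sig + stats::rnorm(n, sd = cfg$noise_rms * peak)
  }
  series_like(command, sig)
}

#' Generate a reference trial (EMG plus ground-truth torque)
#'
#' Round-trip harness: synthesizes one surface-EMG channel per muscle from
#' the command profile and computes a ground-truth joint torque by running
#' the chosen forward contraction model on the *noise-free* command (so
#' estimator error can be separated from fixture noise). For the Hill
#' models the command is used as activation directly (after nonlinear
#' shaping for `"hill_nonlinear"`); for the physiological model the command
#' provides the recruitment ratio and, thresholded, the contraction
#' indicator.
#'
#' @param profile List with `command` and `labels` from [build_command()].
#' @param cfg A [synth_trial_config()].
#' @param forward_model One of `"hill_linear"`, `"hill_nonlinear"`,
#'   `"physio"`.
#' @param joint A [joint_config()].
#' @param A Shape factor for `"hill_nonlinear"` (default -1.7).
#' @param physio_opts Named list for `"physio"`: `Uc`, `Ur`, `km_over_Fm`,
#'   `pi_threshold` (indicator threshold on the command, default 0.02).
#' @param dt_int Integration step passed to the simulators.
#' @return An object of class `synth_trial`: list with `emg` (named list of
#'   [uniform_series()]), `torque` ([uniform_series()], N m),
#'   `labels`, `command`, `seed`.
#' @export
generate_reference_trial <- function(profile, cfg,
                                     forward_model = c("hill_linear",
                                                       "hill_nonlinear",
                                                       "physio"),
                                     joint = joint_config(),
                                     A = -1.7,
                                     physio_opts = list(),
                                     dt_int = 1e-3) {
  forward_model <- match.arg(forward_model)
  stopifnot(inherits(cfg, "synth_trial_config"),
            inherits(joint, "joint_config"))
  command <- profile$command

  emg <- list()
  seed_i <- cfg$seed
  for (nm in names(joint$muscles)) {
    emg[[nm]] <- generate_surface_emg(command, cfg, seed = seed_i)
    seed_i <- seed_i + 1L
  }

  torque <- forward_torque(command, forward_model, joint, A = A,
                           physio_opts = physio_opts, dt_int = dt_int)

  structure(
    list(
      emg = emg, torque = torque, labels = profile$labels,
      command = command, seed = cfg$seed, forward_model = forward_model
    ),
    class = "synth_trial"
  )
}

#' Forward joint torque from a clean command
#'
#' Runs a contraction model per muscle on a known activation command and
#' assembles the (unnormalized) joint torque in N m.
#'
#' @inheritParams generate_reference_trial
#' @param command Activation command in `[0, 1]` as a [uniform_series()].
#' @return Joint torque as a [uniform_series()] (N m).
#' @export
forward_torque <- function(command,
                           forward_model = c("hill_linear", "hill_nonlinear",
                                             "physio"),
                           joint = joint_config(), A = -1.7,
                           physio_opts = list(), dt_int = 1e-3) {
  forward_model <- match.arg(forward_model)
  stopifnot(is_uniform_series(command), inherits(joint, "joint_config"))
  po <- utils::modifyList(
    list(Uc = 5, Ur = 10, km_over_Fm = 20, pi_threshold = 0.02),
    physio_opts
  )
  torques <- list()
  for (nm in names(joint$muscles)) {
    mt <- joint$muscles[[nm]]
    Fc <- switch(
      forward_model,
      hill_linear = simulate_hill(command, mt, dt_int = dt_int)$Fc,
      hill_nonlinear = simulate_hill(
        muscle_activation(command, A), mt, dt_int = dt_int
      )$Fc,
      physio = {
        pi_c <- series_like(command,
                            as.numeric(command$values > po$pi_threshold))
        drive <- chemical_drive_from_indicator(pi_c, Uc = po$Uc, Ur = po$Ur)
        pp <- physio_params(mt, Uc = po$Uc, Ur = po$Ur,
                            km_over_Fm = po$km_over_Fm)
        simulate_physio(drive, command, pp, dt_int = dt_int)$Fc
      }
    )
    torques[[nm]] <- muscle_torque(Fc, mt$phi, joint$moment_arm[[nm]])
  }
  total <- torques[[1]]$values
  if (length(torques) > 1L) {
    for (i in seq(2L, length(torques))) total <- total + torques[[i]]$values
  }
  series_like(command, total)
}
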