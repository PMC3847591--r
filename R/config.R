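#' Load a run configuration from YAML
#'
#' Reads and validates the single configuration file that drives synthesis,
#' estimation and comparison, so that all three contraction models share
#' every common parameter. Unknown keys are rejected to catch typos early.
#' See [default_run_config()] for the schema and defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return An object of class `run_config`: list with fields `model`,
#'   `seed`, `envelope` ([envelope_config()]), `activation`
#'   ([activation_params()]), `joint` ([joint_config()]), `physio` (named
#'   list), `synth` ([synth_trial_config()]), `io` (named list of paths).
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build_run_config(raw)
}

#' Default run configuration
#'
#' @return A `run_config` populated with the package defaults: linear Hill
#'   model, 30/4 Hz high-pass, 2/2 Hz low-pass, 40 ms delay, `C1 = C2 =
#'   -0.5`, `A = -1.7`, gastrocnemius + soleus with the printed moment
#'   arms, chemical rates 5 and 10 1/s.
#' @export
default_run_config <- function() build_run_config(list())

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

pick <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]

build_run_config <- function(raw) {
  check_keys(raw, c("model", "seed", "envelope", "activation", "muscle",
                    "physio", "joint", "synth", "io"), "config")
  model <- pick(raw, "model", "hill_linear")
  if (!model %in% c("hill_linear", "hill_nonlinear", "physio")) {
    stop(sprintf("unknown model '%s'", model))
  }

  env_raw <- pick(raw, "envelope", list())
  check_keys(env_raw, c("hp_cutoff", "hp_order", "lp_cutoff", "lp_order",
                        "mav_window"), "envelope:")
  envelope <- envelope_config(
    hp_cutoff = pick(env_raw, "hp_cutoff", 30),
    hp_order = pick(env_raw, "hp_order", 4),
    lp_cutoff = pick(env_raw, "lp_cutoff", 2),
    lp_order = pick(env_raw, "lp_order", 2),
    mav_window = env_raw$mav_window
  )

  act_raw <- pick(raw, "activation", list())
  check_keys(act_raw, c("d_ms", "C1", "C2", "A"), "activation:")
  activation <- activation_params(
    C1 = pick(act_raw, "C1", -0.5),
    C2 = pick(act_raw, "C2", -0.5),
    d_s = pick(act_raw, "d_ms", 40) / 1000,
    A = pick(act_raw, "A", -1.7)
  )

  mus_raw <- pick(raw, "muscle", list())
  muscles <- list()
  arms <- c()
  if (length(mus_raw) == 0L) {
    muscles <- list(GAS = gas_params(), SOL = sol_params())
    arms <- c(GAS = 0.0515, SOL = 0.0464)
  } else {
    for (nm in names(mus_raw)) {
      m <- mus_raw[[nm]]
      check_keys(m, c("Fm_N", "Lc0_cm", "Lt0_cm", "pennation_deg",
                      "kt_N_per_mm", "b", "Vsh", "vmax_Lc0_per_s",
                      "moment_arm_m"), sprintf("muscle: %s:", nm))
      muscles[[nm]] <- muscle_tendon_params(
        Fm = m$Fm_N, Lc0 = m$Lc0_cm / 100, Lt0 = m$Lt0_cm / 100,
        pennation_deg = m$pennation_deg,
        kt = pick(m, "kt_N_per_mm", 180) * 1000,
        b = pick(m, "b", 0.5), Vsh = pick(m, "Vsh", 0.3),
        vmax_rel = pick(m, "vmax_Lc0_per_s", 10)
      )
      arms[nm] <- m$moment_arm_m
    }
  }
  joint_raw <- pick(raw, "joint", list())
  check_keys(joint_raw, c("mvc_torque_Nm"), "joint:")
  joint <- joint_config(muscles = muscles, moment_arm = arms,
                        mvc_torque = joint_raw$mvc_torque_Nm)

  phys_raw <- pick(raw, "physio", list())
  check_keys(phys_raw, c("Uc", "Ur", "km_over_Fm", "threshold_frac_mvc",
                         "recruitment_mode", "dt_int_ms"), "physio:")
  physio <- list(
    Uc = pick(phys_raw, "Uc", 5),
    Ur = pick(phys_raw, "Ur", 10),
    km_over_Fm = pick(phys_raw, "km_over_Fm", 20),
    threshold_frac_mvc = pick(phys_raw, "threshold_frac_mvc", 0.05),
    recruitment_mode = pick(phys_raw, "recruitment_mode", "continuous")
  )
  dt_int <- pick(phys_raw, "dt_int_ms", 1) / 1000

  seed <- as.integer(pick(raw, "seed", 1L))
  synth_raw <- pick(raw, "synth", list())
  check_keys(synth_raw, c("fs", "n_motor_units", "firing_rate_min_hz",
                          "firing_rate_max_hz", "ap_duration_ms",
                          "noise_rms"), "synth:")
  synth <- synth_trial_config(
    fs = pick(synth_raw, "fs", 2048),
    n_motor_units = pick(synth_raw, "n_motor_units", 50),
    firing_rate_range = c(pick(synth_raw, "firing_rate_min_hz", 8),
                          pick(synth_raw, "firing_rate_max_hz", 35)),
    ap_duration = pick(synth_raw, "ap_duration_ms", 8) / 1000,
    noise_rms = pick(synth_raw, "noise_rms", 0.02),
    seed = seed
  )

  io_raw <- pick(raw, "io", list())
  check_keys(io_raw, c("out_dir", "mvc_trial"), "io:")
  io <- list(
    out_dir = pick(io_raw, "out_dir", "trials"),
    mvc_trial = pick(io_raw, "mvc_trial", file.path(
      pick(io_raw, "out_dir", "trials"), "mvc.csv"
    ))
  )

  structure(
    list(model = model, seed = seed, envelope = envelope,
         activation = activation, joint = joint, physio = physio,
         dt_int = dt_int, synth = synth, io = io),
    class = "run_config"
  )
}

#' Synthesize the default labelled trial set
#'
#' Writes five labelled trials to the configured output directory: `mvc`,
#' `plateau30`, `plateau70` and two randomized fast/slow trials, each as a
#' standard trial CSV plus JSON sidecar. The measured-torque column holds
#' the ground truth produced by the configured forward model on the clean
#' command. Deterministic per seed.
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @return Character vector of the written CSV paths, invisibly.
#' @export
run_synth <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$io$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    mvc = segments_mvc(),
    plateau30 = segments_plateau(0.3),
    plateau70 = segments_plateau(0.7),
    random1 = segments_random(config$seed),
    random2 = segments_random(config$seed + 1L)
  )
  paths <- character(0)
  seed_i <- config$seed
  for (nm in names(specs)) {
    profile <- build_command(specs[[nm]], config$synth$fs)
    cfg <- config$synth
    cfg$seed <- seed_i
    trial <- generate_reference_trial(
      profile, cfg, forward_model = config$model, joint = config$joint,
      A = config$activation$A,
      physio_opts = config$physio[c("Uc", "Ur", "km_over_Fm")],
      dt_int = config$dt_int
    )
    p <- file.path(out, paste0(nm, ".csv"))
    write_trial(trial, p)
    paths <- c(paths, p)
    seed_i <- seed_i + 10L
  }
  invisible(paths)
}

#' Estimate torque for a trial file
#'
#' Loads a trial and the configured MVC trial, runs the configured model
#' through [estimate_torque()], and writes `<trial>_<model>_estimate.csv`
#' (time, normalized estimate, normalized measurement when present) and
#' `<trial>_<model>_metrics.csv` next to the trial.
#'
#' @param config A `run_config`.
#' @param trial_path Path to a trial CSV.
#' @param models Models to run (default: the configured one).
#' @return The metrics `data.frame`, invisibly.
#' @export
run_estimate <- function(config, trial_path, models = config$model) {
  stopifnot(inherits(config, "run_config"))
  trial <- read_trial(trial_path)
  mvc <- read_trial(config$io$mvc_trial)
  metrics <- evaluate_models(
    trial, mvc, models = models,
    envelope = config$envelope, activation = config$activation,
    joint = config$joint, physio = config$physio, dt_int = config$dt_int
  )
  stem <- sub("\\.csv$", "", trial_path)
  for (m in models) {
    est <- estimate_torque(
      trial, mvc, model = m,
      envelope = config$envelope, activation = config$activation,
      joint = config$joint, physio = config$physio, dt_int = config$dt_int
    )
    df <- data.frame(time_s = time_points(est$torque),
                     torque_norm_est = est$torque$values)
    if (!is.null(trial$torque)) {
      df$torque_norm_meas <- trial$torque$values / max(mvc$torque$values)
    }
    utils::write.csv(df, sprintf("%s_%s_estimate.csv", stem, m),
                     row.names = FALSE)
  }
  utils::write.csv(metrics, sprintf("%s_%s_metrics.csv", stem,
                                    paste(models, collapse = "-")),
                   row.names = FALSE)
  invisible(metrics)
}

#' Calibrate the shape factor from an MVC trial
#'
#' Runs [calibrate_shape_factor()] with the nonlinear Hill estimator as the
#' model runner, against the measured MVC-trial torque.
#'
#' @param config A `run_config`.
#' @param mvc_path Path to the MVC trial CSV (defaults to the configured
#'   one).
#' @return The calibrated `A`.
#' @export
run_calibrate_A <- function(config, mvc_path = config$io$mvc_trial) {
  stopifnot(inherits(config, "run_config"))
  mvc <- read_trial(mvc_path)
  if (is.null(mvc$torque)) stop("MVC trial has no measured torque")
  measured <- series_like(mvc$torque,
                          mvc$torque$values / max(mvc$torque$values))
  act <- config$activation
  runner <- function(A) {
    act$A <- A
    estimate_torque(mvc, mvc, model = "hill_nonlinear",
                    envelope = config$envelope, activation = act,
                    joint = config$joint, physio = config$physio,
                    dt_int = config$dt_int)$torque
  }
  calibrate_shape_factor(measured, runner)
}
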