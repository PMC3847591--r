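#' EMG-to-torque estimation pipeline
#'
#' Runs the full estimation chain on a trial, for one of the three
#' contraction models, normalizing everything against an MVC trial:
#' \enumerate{
#'   \item per muscle, the raw EMG is conditioned into an envelope `e(t)`
#'     normalized by the peak of the processed MVC-trial envelope;
#'   \item the activation recursion produces neural activation `p(t)`;
#'   \item `model = "hill_linear"` uses `a = p`; `"hill_nonlinear"` applies
#'     the exponential shaping with factor `A`; `"physio"` derives the
#'     chemical drive from the 30 Hz envelope of the same raw EMG
#'     (threshold = `threshold_frac_mvc` times the MVC peak of that
#'     envelope, delayed by the electromechanical delay) and uses `p` as
#'     the recruitment input;
#'   \item the per-muscle forces are turned into joint torque with
#'     pennation and moment arms, summed, and divided by the peak torque
#'     the same model produces on the MVC trial.
#' }
#'
#' @param trial Trial as returned by [read_trial()] or
#'   [generate_reference_trial()] (list with `emg`, optional `torque`).
#' @param mvc_trial MVC trial in the same format (used for all
#'   normalizations).
#' @param model One of `"hill_linear"`, `"hill_nonlinear"`, `"physio"`.
#' @param envelope An [envelope_config()].
#' @param activation An [activation_params()]; its `A` is used by the
#'   nonlinear Hill model and its delay by all models.
#' @param joint A [joint_config()]; muscle names must match the trial's
#'   EMG channels.
#' @param physio Named list of physiological-model settings: `Uc`, `Ur`,
#'   `km_over_Fm`, `threshold_frac_mvc` (default 0.05), `recruitment_mode`
#'   (default `"continuous"`).
#' @param dt_int Integration step in seconds.
#' @return An object of class `torque_estimate`: list with `torque`
#'   (MVC-normalized [uniform_series()]), `torque_Nm` (unnormalized),
#'   `mvc_torque_Nm` (normalization constant), `per_muscle` (list of force
#'   traces) and `model`.
#' @export
estimate_torque <- function(trial, mvc_trial,
                            model = c("hill_linear", "hill_nonlinear",
                                      "physio"),
                            envelope = envelope_config(),
                            activation = activation_params(),
                            joint = joint_config(),
                            physio = list(),
                            dt_int = 1e-3) {
  model <- match.arg(model)
  po <- utils::modifyList(
    list(Uc = 5, Ur = 10, km_over_Fm = 20, threshold_frac_mvc = 0.05,
         recruitment_mode = "continuous"),
    physio
  )
  muscles <- names(joint$muscles)
  if (!all(muscles %in% names(trial$emg))) {
    stop(sprintf(
      "trial is missing EMG channels for: %s",
      paste(setdiff(muscles, names(trial$emg)), collapse = ", ")
    ))
  }

  run_unnormalized <- function(tr) {
    torques <- list()
    for (nm in muscles) {
      mt <- joint$muscles[[nm]]
      raw <- tr$emg[[nm]]
      mvc_raw <- mvc_trial$emg[[nm]]

      env_cfg_nopk <- envelope
      env_cfg_nopk$mvc_peak <- NULL
      mvc_peak <- max(process_emg(mvc_raw, env_cfg_nopk)$values)
      e <- normalize_mvc(process_emg(raw, env_cfg_nopk), mvc_peak)
      e <- series_like(e, pmin(pmax(e$values, 0), 1))
      p <- neural_activation(e, activation)
      p <- series_like(p, pmin(pmax(p$values, 0), 1))

      Fc <- switch(
        model,
        hill_linear = simulate_hill(p, mt, dt_int = dt_int)$Fc,
        hill_nonlinear = simulate_hill(
          muscle_activation(p, activation$A), mt, dt_int = dt_int
        )$Fc,
        physio = {
          mvc_chem_peak <- max(make_chemical_input(
            mvc_raw, envelope, threshold = .Machine$double.xmin,
            Uc = po$Uc, Ur = po$Ur
          )$envelope$values)
          drive <- make_chemical_input(
            raw, envelope, threshold = po$threshold_frac_mvc * mvc_chem_peak,
            Uc = po$Uc, Ur = po$Ur, delay_s = activation$d_s
          )
          alpha <- recruitment_alpha(p, drive$pi_c, po$recruitment_mode)
          pp <- physio_params(mt, Uc = po$Uc, Ur = po$Ur,
                              km_over_Fm = po$km_over_Fm)
          simulate_physio(drive, alpha, pp, dt_int = dt_int)$Fc
        }
      )
      torques[[nm]] <- muscle_torque(Fc, mt$phi, joint$moment_arm[[nm]])
    }
    total <- torques[[1]]$values
    if (length(torques) > 1L) {
      for (i in seq(2L, length(torques))) total <- total + torques[[i]]$values
    }
    list(total = series_like(torques[[1]], total), per_muscle = torques)
  }

  mvc_run <- run_unnormalized(mvc_trial)
  mvc_torque <- max(mvc_run$total$values)
  if (mvc_torque <= 0) stop("MVC trial produced no torque; check inputs")
  est <- run_unnormalized(trial)

  structure(
    list(
      torque = series_like(est$total, est$total$values / mvc_torque),
      torque_Nm = est$total,
      mvc_torque_Nm = mvc_torque,
      per_muscle = est$per_muscle,
      model = model
    ),
    class = "torque_estimate"
  )
}

#' @export
print.torque_estimate <- function(x, ...) {
  cat(sprintf(
    "<torque_estimate> model = %s, %d samples, peak = %.3f (normalized), MVC = %.2f N m\n",
    x$model, length(x$torque), max(x$torque$values), x$mvc_torque_Nm
  ))
  invisible(x)
}

# Index windows per segment label; fast/slow windows come from the
# fixture's ground-truth labels (segmentation is by protocol, not detected).
label_windows <- function(labels) {
  stopifnot(is.character(labels))
  out <- list(whole = seq_along(labels))
  for (lb in setdiff(unique(labels), "rest")) {
    out[[lb]] <- which(labels == lb)
  }
  out
}

#' Evaluate one or more models against measured torque
#'
#' Runs [estimate_torque()] for each requested model and compares the
#' MVC-normalized estimate with the measured torque, normalized by the
#' measured MVC-trial peak. Per segment label (plus `"whole"`), the RMS
#' error is reported; for `fast_short` segments the peak error is reported
#' as well.
#'
#' @inheritParams estimate_torque
#' @param models Character vector of models to run.
#' @param labels Per-sample segment labels; defaults to the trial's own.
#' @return `data.frame` with columns `segment`, `model`, `rms`,
#'   `peak_error` (NA where not applicable), mirroring the package's
#'   report layout.
#' @export
evaluate_models <- function(trial, mvc_trial,
                            models = c("hill_linear", "hill_nonlinear",
                                       "physio"),
                            labels = trial$labels,
                            envelope = envelope_config(),
                            activation = activation_params(),
                            joint = joint_config(),
                            physio = list(),
                            dt_int = 1e-3) {
  if (is.null(trial$torque)) stop("trial has no measured torque to compare")
  if (is.null(labels)) labels <- rep("whole", length(trial$torque))
  meas_mvc_peak <- if (!is.null(mvc_trial$torque)) {
    max(mvc_trial$torque$values)
  } else {
    stop("MVC trial has no measured torque for normalization")
  }
  measured <- series_like(trial$torque, trial$torque$values / meas_mvc_peak)
  windows <- label_windows(labels)

  rows <- list()
  for (m in models) {
    est <- estimate_torque(trial, mvc_trial, model = m,
                           envelope = envelope, activation = activation,
                           joint = joint, physio = physio, dt_int = dt_int)
    for (seg in names(windows)) {
      idx <- windows[[seg]]
      pe <- if (grepl("fast", seg)) {
        peak_error(est$torque, measured, idx)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg, model = m,
        rms = rms_error(est$torque, measured, idx),
        peak_error = pe
      )
    }
  }
  do.call(rbind, rows)
}
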