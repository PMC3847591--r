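#' Ankle joint configuration
#'
#' Moment arms and per-muscle parameter sets for assembling plantar-flexion
#' torque from muscle forces. Defaults carry the printed moment arms for the
#' medial gastrocnemius (0.0515 m) and the soleus (0.0464 m) at the measured
#' joint posture.
#'
#' @param muscles Named list of [muscle_tendon_params()] (at least one).
#' @param moment_arm Named numeric vector of moment arms in m, aligned with
#'   `muscles`.
#' @param mvc_torque Optional MVC torque in N m used for normalization.
#' @return An object of class `joint_config`.
#' @export
joint_config <- function(muscles = list(GAS = gas_params(), SOL = sol_params()),
                         moment_arm = c(GAS = 0.0515, SOL = 0.0464),
                         mvc_torque = NULL) {
  if (length(muscles) < 1L) stop("at least one muscle is required")
  if (!setequal(names(muscles), names(moment_arm)) ||
      length(moment_arm) != length(muscles)) {
    stop("'moment_arm' must be named to match 'muscles'")
  }
  if (any(moment_arm <= 0)) stop("moment arms must be > 0")
  if (!is.null(mvc_torque) && (!is.finite(mvc_torque) || mvc_torque <= 0)) {
    stop("'mvc_torque' must be > 0")
  }
  structure(
    list(
      muscles = muscles,
      moment_arm = moment_arm[names(muscles)],
      mvc_torque = mvc_torque
    ),
    class = "joint_config"
  )
}

#' Muscle torque about the joint
#'
#' Rotates the CE force onto the tendon axis with the pennation angle and
#' multiplies by the moment arm: `torque = Fc cos(phi) * arm`.
#'
#' @param Fc Muscle force in N as a [uniform_series()].
#' @param phi Pennation angle in radians.
#' @param moment_arm Moment arm in m.
#' @return Torque in N m as a [uniform_series()].
#' @export
muscle_torque <- function(Fc, phi, moment_arm) {
  stopifnot(is_uniform_series(Fc))
  series_like(Fc, Fc$values * cos(phi) * moment_arm)
}

#' Relative torque contribution of each muscle
#'
#' Fraction of the maximal joint torque contributed by each muscle, computed
#' from the maximum isometric force, the pennation angle and the moment arm:
#' `frac_i = Fm_i cos(phi_i) arm_i / sum_j Fm_j cos(phi_j) arm_j`. With the
#' default gastrocnemius/soleus sets this yields 0.41 / 0.59 after rounding
#' to two decimals.
#'
#' @param cfg A [joint_config()] with at least two muscles.
#' @return Named numeric vector of fractions summing to 1 (full precision;
#'   round only for reporting).
#' @export
contribution_ratio <- function(cfg) {
  stopifnot(inherits(cfg, "joint_config"))
  if (length(cfg$muscles) < 2L) {
    stop("contribution ratios need at least two muscles")
  }
  w <- vapply(
    names(cfg$muscles),
    function(nm) {
      m <- cfg$muscles[[nm]]
      m$Fm * cos(m$phi) * cfg$moment_arm[[nm]]
    },
    numeric(1)
  )
  w / sum(w)
}

#' MVC-normalized summed joint torque
#'
#' Sums per-muscle torque series and divides by the MVC torque, so that an
#' MVC trial maps to a peak of about 1.
#'
#' @param per_muscle List of torque [uniform_series()] on a shared time
#'   base.
#' @param cfg A [joint_config()] with `mvc_torque` set.
#' @return Normalized torque as a [uniform_series()].
#' @export
normalized_sum_torque <- function(per_muscle, cfg) {
  stopifnot(inherits(cfg, "joint_config"), length(per_muscle) >= 1L)
  if (is.null(cfg$mvc_torque)) {
    stop("'mvc_torque' must be set in the joint_config for normalization")
  }
  total <- per_muscle[[1]]$values
  if (length(per_muscle) > 1L) {
    for (i in seq(2L, length(per_muscle))) {
      check_same_time_base(per_muscle[[1]], per_muscle[[i]],
                           "per-muscle torques")
      total <- total + per_muscle[[i]]$values
    }
  }
  series_like(per_muscle[[1]], total / cfg$mvc_torque)
}

# Resolve an optional index window against a series length.
resolve_window <- function(n, window) {
  if (is.null(window)) return(seq_len(n))
  window <- as.integer(window)
  if (length(window) == 0L || any(window < 1L) || any(window > n)) {
    stop("window is empty or out of range")
  }
  window
}

#' Root-mean-square error between two series
#'
#' RMS of the pointwise difference over the whole trial or a labelled index
#' window (e.g. a slow-long or fast-short segment). Both series are expected
#' on the same (typically MVC-normalized) scale.
#'
#' @param estimated,measured [uniform_series()] on a shared time base.
#' @param window Optional integer index range.
#' @return Nonnegative scalar.
#' @export
rms_error <- function(estimated, measured, window = NULL) {
  stopifnot(is_uniform_series(estimated), is_uniform_series(measured))
  check_same_time_base(estimated, measured, "'estimated' and 'measured'")
  idx <- resolve_window(length(estimated$values), window)
  sqrt(mean((estimated$values[idx] - measured$values[idx])^2))
}

#' Peak error over a burst window
#'
#' Absolute difference between the maxima of the estimated and the measured
#' series over a burst window. Peaks are compared, not samples, so the
#' metric is insensitive to small alignment shifts within the window.
#'
#' @param estimated,measured [uniform_series()] on a shared time base.
#' @param burst_window Integer index range covering the burst.
#' @return Nonnegative scalar.
#' @export
peak_error <- function(estimated, measured, burst_window) {
  stopifnot(is_uniform_series(estimated), is_uniform_series(measured))
  check_same_time_base(estimated, measured, "'estimated' and 'measured'")
  idx <- resolve_window(length(estimated$values), burst_window)
  abs(max(estimated$values[idx]) - max(measured$values[idx]))
}

#' Calibrate the nonlinear shape factor on an MVC trial
#'
#' Finds the shape factor `A` in `[-3, 0)` minimizing the RMS difference
#' between the measured MVC-trial torque and the model estimate produced by
#' `model_runner(A)`. Bounded scalar minimization (golden-section /
#' parabolic) is combined with an endpoint check so that boundary optima are
#' returned exactly; the result is deterministic given the inputs.
#'
#' @param measured_mvc Measured normalized torque as a [uniform_series()].
#' @param model_runner Function taking `A` and returning the estimated
#'   torque [uniform_series()] on the same time base.
#' @param lower,upper Search bounds (defaults -3 and just below 0).
#' @return The calibrated `A`.
#' @export
calibrate_shape_factor <- function(measured_mvc, model_runner,
                                   lower = -3, upper = -1e-6) {
  stopifnot(is_uniform_series(measured_mvc), is.function(model_runner))
  objective <- function(A) {
    out <- rms_error(model_runner(A), measured_mvc)
    if (!is.finite(out)) {
      stop(sprintf("calibration objective is non-finite at A = %g", A))
    }
    out
  }
  opt <- stats::optimize(objective, lower = lower, upper = upper,
                         tol = 1e-6)
  cand_A <- c(opt$minimum, lower, upper)
  cand_val <- c(opt$objective, objective(lower), objective(upper))
  cand_A[which.min(cand_val)]
}
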