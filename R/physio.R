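#' Multi-scale contractile-element parameters
#'
#' Parameters of the cross-bridge distribution-moment contractile element.
#' The sarcomere-scale two-state attachment/detachment kinetics reduce
#' exactly to ordinary differential equations for the whole-CE active
#' stiffness `kc` and force `Fc` because the rate functions do not depend on
#' the bond coordinate. `Uc` and `Ur` are the chemical kinetic rates during
#' contraction and relaxation; `km0` is the maximum active stiffness scale,
#' set by default to `20 * Fm` (numerically, in N/m) from the observation
#' that active muscle stiffness reaches the tendon stiffness near maximal
#' contraction. The force-length relation acts at the microscopic scale by
#' scaling the number of available attachment sites, so the effective
#' maxima are `km0 * fl(eps_c)` and `Fm * fl(eps_c)`.
#'
#' @param mt A [muscle_tendon_params()] providing `Fm`, `Lc0`, `Lt0`,
#'   pennation, `kt` and the force-length width `b`.
#' @param Uc Contraction kinetic rate in 1/s (default 5).
#' @param Ur Relaxation kinetic rate in 1/s (default 10).
#' @param km_over_Fm Ratio `km0 / Fm` in 1/m (default 20).
#'
#' @return An object of class `physio_params`.
#' @export
physio_params <- function(mt, Uc = 5, Ur = 10, km_over_Fm = 20) {
  stopifnot(inherits(mt, "muscle_tendon_params"))
  if (any(!is.finite(c(Uc, Ur, km_over_Fm))) ||
      Uc <= 0 || Ur <= 0 || km_over_Fm <= 0) {
    stop("'Uc', 'Ur' and 'km_over_Fm' must be strictly positive")
  }
  structure(
    list(
      Uc = Uc, Ur = Ur,
      km0 = km_over_Fm * mt$Fm,
      Fm = mt$Fm, Lc0 = mt$Lc0, Lt0 = mt$Lt0,
      phi = mt$phi, kt = mt$kt, b = mt$b
    ),
    class = "physio_params"
  )
}

#' Chemical input from raw EMG
#'
#' Builds the two-level chemical drive of the multi-scale model. The raw EMG
#' is high-pass filtered (artifact removal), rectified and low-pass filtered
#' at 30 Hz (zero-lag); the contraction indicator `Pi_c(t)` is 1 where this
#' 30 Hz envelope exceeds the threshold and 0 elsewhere, standing in for the
#' all-or-nothing calcium-triggered contraction state. The combined kinetic
#' rate is `u(t) = Pi_c Uc + (1 - Pi_c) Ur`. An optional delay shifts the
#' indicator to account for the electromechanical delay (action-potential
#' propagation plus calcium dynamics).
#'
#' The threshold is meant to sit a little above the baseline; the estimate
#' is insensitive to its exact value because the activation level itself is
#' carried by the recruitment input, not by `Pi_c`.
#'
#' @param emg_raw Raw EMG as a [uniform_series()].
#' @param cfg An [envelope_config()] supplying the high-pass settings.
#' @param threshold Positive threshold in the units of the 30 Hz envelope.
#' @param Uc,Ur Kinetic rates in 1/s.
#' @param lp_cutoff Cutoff of the chemical-envelope low-pass in Hz
#'   (default 30).
#' @param lp_order Effective order of that zero-lag low-pass (default 2).
#' @param delay_s Delay applied to the indicator in seconds (default 0).
#'
#' @return An object of class `chemical_drive`: list with `pi_c` (binary
#'   [uniform_series()]), `u` ([uniform_series()], 1/s), `envelope` (the
#'   30 Hz envelope) and `threshold`.
#' @export
make_chemical_input <- function(emg_raw, cfg = envelope_config(), threshold,
                                Uc = 5, Ur = 10,
                                lp_cutoff = 30, lp_order = 2, delay_s = 0) {
  stopifnot(is_uniform_series(emg_raw), inherits(cfg, "envelope_config"))
  if (!is.finite(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  env <- zero_lag_butterworth(
    rectify(zero_lag_butterworth(emg_raw, cfg$hp_cutoff, cfg$hp_order, "high")),
    lp_cutoff, lp_order, "low"
  )
  if (threshold > max(env$values)) {
    warning("threshold exceeds the envelope maximum; Pi_c is identically 0")
  }
  pi_c <- as.numeric(env$values > threshold)
  d <- as.integer(round(delay_s / emg_raw$dt))
  if (d > 0) {
    pi_c <- c(numeric(d), pi_c[seq_len(length(pi_c) - d)])
  }
  u <- pi_c * Uc + (1 - pi_c) * Ur
  structure(
    list(
      pi_c = series_like(emg_raw, pi_c),
      u = series_like(emg_raw, u),
      envelope = env,
      threshold = threshold, Uc = Uc, Ur = Ur
    ),
    class = "chemical_drive"
  )
}

#' Constructed chemical drive
#'
#' Builds a `chemical_drive` directly from a known contraction indicator,
#' bypassing EMG extraction. Used for forward simulation from a command
#' profile and in tests with analytically known switching times.
#'
#' @param pi_c Binary contraction indicator as a [uniform_series()].
#' @param Uc,Ur Kinetic rates in 1/s.
#' @return A `chemical_drive`.
#' @export
chemical_drive_from_indicator <- function(pi_c, Uc = 5, Ur = 10) {
  stopifnot(is_uniform_series(pi_c))
  v <- pi_c$values
  if (!all(v %in% c(0, 1))) stop("'pi_c' must be binary (0/1)")
  structure(
    list(
      pi_c = pi_c,
      u = series_like(pi_c, v * Uc + (1 - v) * Ur),
      envelope = NULL, threshold = NA_real_, Uc = Uc, Ur = Ur
    ),
    class = "chemical_drive"
  )
}

#' @export
print.chemical_drive <- function(x, ...) {
  v <- x$pi_c$values
  cat(sprintf(
    "<chemical_drive> %d samples, contraction %.1f%% of time, Uc = %g, Ur = %g 1/s\n",
    length(v), 100 * mean(v), x$Uc, x$Ur
  ))
  invisible(x)
}

#' Recruitment input from neural activation
#'
#' Derives the recruitment ratio `alpha(t)` (fraction of recruited motor
#' units) from neural activation `p(t)`. Three conventions are provided for
#' how `alpha` behaves across a contraction phase (a maximal run of
#' `Pi_c = 1`):
#' * `"continuous"` (default): `alpha = p` at every sample;
#' * `"hold_at_onset"`: `alpha` is frozen at `p` of the first sample of each
#'   contraction run;
#' * `"hold_phase_max"`: `alpha` is frozen at the maximum of `p` over the
#'   run.
#' Outside contraction runs `alpha = p` in all modes (it has no effect
#' there, since every recruitment term carries a `Pi_c` factor).
#'
#' @param p Neural activation in `[0, 1]` as a [uniform_series()].
#' @param pi_c Binary contraction indicator on the same time base.
#' @param mode One of `"continuous"`, `"hold_at_onset"`, `"hold_phase_max"`.
#' @return Recruitment ratio `alpha(t)` as a [uniform_series()] in `[0, 1]`.
#' @export
recruitment_alpha <- function(p, pi_c,
                              mode = c("continuous", "hold_at_onset",
                                       "hold_phase_max")) {
  stopifnot(is_uniform_series(p), is_uniform_series(pi_c))
  mode <- match.arg(mode)
  if (length(p) != length(pi_c)) {
    stop("'p' and 'pi_c' must have the same length")
  }
  v <- pmin(pmax(p$values, 0), 1)
  if (mode == "continuous") {
    return(series_like(p, v))
  }
  out <- v
  r <- rle(pi_c$values == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    out[idx] <- if (mode == "hold_at_onset") v[starts[i]] else max(v[idx])
  }
  series_like(p, out)
}

# Shared right-hand side used by physio_rhs() and the integrator.
# state = c(kc, Fc, eps); inputs are scalars; mt_velocity is L0 * eps_dot of
# the whole unit in m/s (0 when isometric). Returns c(dkc, dFc, deps).
physio_deriv <- function(state, u_t, pi_c_t, alpha_t, mt_velocity, pp,
                         eps_dot_forced = NULL) {
  kc <- state[1]
  Fc <- state[2]
  eps <- state[3]
  fl <- force_length(eps, pp$b)
  fm_eps <- pp$Fm * fl
  km_eps <- pp$km0 * fl
  src <- alpha_t * pi_c_t * pp$Uc

  if (is.null(eps_dot_forced)) {
    num <- pp$kt * mt_velocity / cos(pp$phi) + Fc * u_t - src * fm_eps
    s <- sign(num)
    den <- pp$kt * pp$Lc0 / cos(pp$phi) + kc * pp$Lc0 - s * Fc
    if (pp$kt * pp$Lc0 / cos(pp$phi) + kc * pp$Lc0 - Fc <= 0) {
      stop(sprintf(
        paste0(
          "series-elastic consistency condition violated: ",
          "kt*Lc0/cos(phi) + kc*Lc0 - Fc <= 0 (kt = %g N/m, kc = %g N/m, ",
          "Fc = %g N)"
        ),
        pp$kt, kc, Fc
      ))
    }
    eps_dot <- num / den
  } else {
    eps_dot <- eps_dot_forced
  }

  loss <- u_t + abs(eps_dot)
  c(
    -loss * kc + src * km_eps,
    -loss * Fc + src * fm_eps + kc * pp$Lc0 * eps_dot,
    eps_dot
  )
}

#' Right-hand side of the distribution-moment contractile element
#'
#' Time derivatives of the internal state `(kc, Fc, eps_c)` of the
#' multi-scale contractile element coupled to the series tendon. The strain
#' rate follows from equating the tendon force rate with the moment
#' equation for `Fc`:
#' `eps_dot = T / (kt Lc0 / cos(phi) + kc Lc0 - sign(T) Fc)` with numerator
#' `T = kt v_mt / cos(phi) + Fc u - alpha Fm(eps) Pi_c Uc`, where `v_mt` is
#' the whole-unit lengthening velocity (0 when isometric). The moment
#' equations then read
#' `dkc/dt = -(u + |eps_dot|) kc + alpha km(eps) Pi_c Uc` and
#' `dFc/dt = -(u + |eps_dot|) Fc + alpha Fm(eps) Pi_c Uc + kc Lc0 eps_dot`,
#' with `km(eps) = km0 fl(eps)` and `Fm(eps) = Fm fl(eps)`. The detachment
#' loss grows with speed in either direction (hence `|eps_dot|`), the
#' reading of the kinetics that is consistent with the sign factor in the
#' strain-rate denominator.
#'
#' @param state Numeric vector `c(kc, Fc, eps_c)`.
#' @param u_t Combined kinetic rate at this instant, 1/s.
#' @param pi_c_t Contraction indicator (0 or 1).
#' @param alpha_t Recruitment ratio in `[0, 1]`.
#' @param mt_velocity Whole-unit lengthening velocity `L0 * deps/dt` in m/s.
#' @param params A [physio_params()].
#' @return Numeric vector `c(dkc/dt, dFc/dt, deps_c/dt)`.
#' @export
physio_rhs <- function(state, u_t, pi_c_t, alpha_t, mt_velocity, params) {
  stopifnot(inherits(params, "physio_params"), length(state) == 3L)
  physio_deriv(state, u_t, pi_c_t, alpha_t, mt_velocity, params)
}

#' Simulate the multi-scale contractile element
#'
#' Integrates the distribution-moment state `(kc, Fc, eps_c)` with a
#' fixed-step fourth-order Runge-Kutta scheme, holding the inputs constant
#' within each input sample (zero-order hold). The state starts at rest
#' `(0, 0, 0)`. `kc` and `Fc` are clipped at zero after each step (a guard
#' against floating-point undershoot during fast relaxation; engagements
#' are counted). The series-elastic consistency condition
#' `kt Lc0 / cos(phi) + kc Lc0 - Fc > 0` is verified at every evaluation.
#'
#' @param drive A `chemical_drive` (see [make_chemical_input()]).
#' @param alpha Recruitment ratio on the same time base, or a single number.
#' @param params A [physio_params()].
#' @param dt_int Integration step in seconds (default 1 ms); when the input
#'   sampling is finer, the input rate is used.
#' @param mt_velocity Whole-unit lengthening velocity in m/s: `NULL`
#'   (isometric), a single number, or a [uniform_series()] on the drive's
#'   time base.
#' @param eps_c_dot Optional prescribed CE strain rate in 1/s (single number
#'   or [uniform_series()]). When given, the tendon-coupling equation is
#'   bypassed and the moment equations are driven by this strain-rate
#'   history directly (used for clamped-velocity and oracle studies).
#'
#' @return An object of class `physio_trace`: list with `Fc` (N), `kc`
#'   (N/m), `eps_c` (strain), all [uniform_series()] at the input rate, and
#'   `clip_count`, the number of zero-clippings of `kc`/`Fc`.
#' @export
simulate_physio <- function(drive, alpha, params, dt_int = 1e-3,
                            mt_velocity = NULL, eps_c_dot = NULL) {
  stopifnot(inherits(drive, "chemical_drive"),
            inherits(params, "physio_params"))
  pi_v <- drive$pi_c$values
  u_v <- drive$u$values
  n <- length(pi_v)

  alpha_v <- if (is_uniform_series(alpha)) {
    check_same_time_base(drive$pi_c, alpha, "'alpha' and the drive")
    alpha$values
  } else {
    rep(as.numeric(alpha), n)
  }
  if (min(alpha_v) < -1e-9 || max(alpha_v) > 1 + 1e-9) {
    stop("'alpha' must lie in [0, 1]")
  }
  vmt_v <- if (is.null(mt_velocity)) {
    numeric(n)
  } else if (is_uniform_series(mt_velocity)) {
    mt_velocity$values
  } else {
    rep(as.numeric(mt_velocity), n)
  }
  forced <- !is.null(eps_c_dot)
  eps_dot_v <- if (!forced) {
    NULL
  } else if (is_uniform_series(eps_c_dot)) {
    eps_c_dot$values
  } else {
    rep(as.numeric(eps_c_dot), n)
  }

  dt <- drive$pi_c$dt
  n_sub <- max(1L, as.integer(ceiling(dt / dt_int)))
  h <- dt / n_sub

  state <- c(0, 0, 0)
  kc_tr <- numeric(n)
  Fc_tr <- numeric(n)
  eps_tr <- numeric(n)
  clip_count <- 0L

  for (k in seq_len(n)) {
    uk <- u_v[k]
    pk <- pi_v[k]
    ak <- alpha_v[k]
    vk <- vmt_v[k]
    ek <- if (forced) eps_dot_v[k] else NULL
    for (s in seq_len(n_sub)) {
      tryCatch({
        k1 <- physio_deriv(state, uk, pk, ak, vk, params, ek)
        k2 <- physio_deriv(state + h / 2 * k1, uk, pk, ak, vk, params, ek)
        k3 <- physio_deriv(state + h / 2 * k2, uk, pk, ak, vk, params, ek)
        k4 <- physio_deriv(state + h * k3, uk, pk, ak, vk, params, ek)
      }, error = function(e) {
        stop(sprintf("at t = %.4f s: %s",
                     drive$pi_c$t0 + (k - 1) * dt, conditionMessage(e)))
      })
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (state[1] < 0 || state[2] < 0) {
        clip_count <- clip_count + (state[1] < 0) + (state[2] < 0)
        state[1] <- max(state[1], 0)
        state[2] <- max(state[2], 0)
      }
    }
    kc_tr[k] <- state[1]
    Fc_tr[k] <- state[2]
    eps_tr[k] <- state[3]
  }

  structure(
    list(
      Fc = series_like(drive$pi_c, Fc_tr),
      kc = series_like(drive$pi_c, kc_tr),
      eps_c = series_like(drive$pi_c, eps_tr),
      clip_count = clip_count
    ),
    class = "physio_trace"
  )
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf(
    "<physio_trace> %d samples, peak Fc = %.2f N, peak kc = %.1f N/m\n",
    length(x$Fc), max(x$Fc$values), max(x$kc$values)
  ))
  invisible(x)
}

#' Isotonic force-velocity relation of the multi-scale model
#'
#' Algebraic Hill-type force-velocity relation obtained from the moment
#' equations at force equilibrium (`dFc/dt = 0`) during a fully triggered
#' contraction phase: for a concentric strain rate `v = eps_c_dot < 0`,
#' `Fc = (alpha Fm Uc + kc0 Lc0 v) / (Uc - v)`, equivalently
#' `Fc = alpha Fm (1 + A0 v) / (1 - B v)` with
#' `A0 = Lc0 kc0 / (Uc alpha Fm)` and `B = 1 / Uc`. At `v = 0` it returns
#' the isometric value `alpha Fm`, and it decreases monotonically with
#' shortening speed, vanishing at `v = -alpha Fm Uc / (kc0 Lc0)`. The
#' relation is evaluated at optimal length (`fl = 1`).
#'
#' @param params A [physio_params()].
#' @param kc0 Active stiffness entering the isotonic phase, N/m (> 0).
#' @param alpha Recruitment ratio in `(0, 1]`.
#' @param velocity_grid Concentric strain rates in 1/s (each `<= 0`).
#' @return `data.frame` with columns `velocity` (1/s) and `force` (N,
#'   floored at 0).
#' @export
isotonic_force_velocity <- function(params, kc0, alpha, velocity_grid) {
  stopifnot(inherits(params, "physio_params"))
  if (!is.finite(kc0) || kc0 < 0) stop("'kc0' must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  v <- as.numeric(velocity_grid)
  if (any(v > 0)) stop("velocities must be concentric (eps_c_dot <= 0)")
  if (any(params$Uc - v <= 0)) stop("require Uc - eps_c_dot > 0")
  force <- (alpha * params$Fm * params$Uc + kc0 * params$Lc0 * v) /
    (params$Uc - v)
  data.frame(velocity = v, force = pmax(force, 0))
}
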