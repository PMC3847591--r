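#' Muscle-tendon macroscopic parameters
#'
#' Constants of the common macroscopic muscle-tendon unit shared by all
#' contraction models: a contractile element (CE) in series with a linear
#' elastic tendon, with the CE force rotated onto the tendon axis by the
#' pennation angle. The parallel elastic element is omitted: its length does
#' not change in the isometric conditions the package targets.
#'
#' @param Fm Maximum isometric CE force in N.
#' @param Lc0 CE rest length in m.
#' @param Lt0 Tendon rest length in m.
#' @param pennation_deg Pennation angle in degrees, in `[0, 90)`.
#' @param kt Linear tendon stiffness in N/m (default 180 N/mm = 1.8e5 N/m,
#'   a literature value for the human triceps surae).
#' @param b Width of the Gaussian force-length relation (strain units),
#'   default 0.5.
#' @param Vsh Shape parameter of the concentric force-velocity hyperbola,
#'   default 0.3.
#' @param vmax_rel Maximum shortening speed in CE rest lengths per second;
#'   `vmax = vmax_rel * Lc0` m/s. Default 10 optimal lengths per second, a
#'   standard mixed-fiber figure (no source value is pinned; adjust per
#'   muscle if known).
#'
#' @return An object of class `muscle_tendon_params` with fields `Fm`,
#'   `Lc0`, `Lt0`, `phi` (radians), `kt`, `b`, `Vsh`, `vmax` (m/s).
#' @seealso [gas_params()], [sol_params()] for ready-made parameter sets.
#' @export
muscle_tendon_params <- function(Fm, Lc0, Lt0, pennation_deg,
                                 kt = 1.8e5, b = 0.5, Vsh = 0.3,
                                 vmax_rel = 10) {
  if (any(!is.finite(c(Fm, Lc0, Lt0, pennation_deg, kt, b, Vsh, vmax_rel)))) {
    stop("all parameters must be finite")
  }
  if (Fm <= 0 || Lc0 <= 0 || Lt0 <= 0 || kt <= 0) {
    stop("forces, lengths and stiffnesses must be strictly positive")
  }
  if (pennation_deg < 0 || pennation_deg >= 90) {
    stop("'pennation_deg' must lie in [0, 90)")
  }
  if (b <= 0 || Vsh <= 0 || vmax_rel <= 0) {
    stop("'b', 'Vsh' and 'vmax_rel' must be strictly positive")
  }
  structure(
    list(
      Fm = Fm, Lc0 = Lc0, Lt0 = Lt0,
      phi = pennation_deg * pi / 180,
      kt = kt, b = b, Vsh = Vsh, vmax = vmax_rel * Lc0
    ),
    class = "muscle_tendon_params"
  )
}

#' Medial gastrocnemius parameter set
#'
#' Literature values for the (two-headed) gastrocnemius acting at the ankle:
#' maximum isometric force 1600 N, CE rest length 5.1 cm, tendon rest length
#' 40 cm, pennation 14 degrees, shared tendon stiffness 180 N/mm.
#'
#' @param ... Overrides passed on to [muscle_tendon_params()].
#' @return A `muscle_tendon_params` object.
#' @export
gas_params <- function(...) {
  defaults <- list(Fm = 1600, Lc0 = 0.051, Lt0 = 0.40, pennation_deg = 14)
  do.call(muscle_tendon_params, utils::modifyList(defaults, list(...)))
}

#' Soleus parameter set
#'
#' Literature values for the soleus: maximum isometric force 2830 N, CE rest
#' length 3.0 cm, tendon rest length 26.8 cm, pennation 30 degrees, shared
#' tendon stiffness 180 N/mm.
#'
#' @param ... Overrides passed on to [muscle_tendon_params()].
#' @return A `muscle_tendon_params` object.
#' @export
sol_params <- function(...) {
  defaults <- list(Fm = 2830, Lc0 = 0.030, Lt0 = 0.268, pennation_deg = 30)
  do.call(muscle_tendon_params, utils::modifyList(defaults, list(...)))
}

#' Force-length relation
#'
#' Gaussian scaling of the maximal CE force with strain around the optimal
#' length: `fl(eps) = exp(-(eps / b)^2)`, an even function equal to 1 at the
#' optimum.
#'
#' @param eps_c CE strain (dimensionless).
#' @param b Width parameter (> 0).
#' @return Value(s) in `(0, 1]`.
#' @export
force_length <- function(eps_c, b) {
  if (!is.finite(b) || b <= 0) stop("'b' must be > 0")
  exp(-(eps_c / b)^2)
}

#' Concentric force-velocity relation
#'
#' Hyperbolic scaling of CE force with shortening speed,
#' `fv = Vsh (vmax + Lc0 eps_dot) / (Vsh vmax - Lc0 eps_dot)` for concentric
#' strain rates (`eps_dot < 0`). Lengthening is outside the modeled scope:
#' for `eps_dot >= 0` the relation is clamped at the isometric value 1.
#' Velocities at or beyond the maximum shortening speed return 0.
#'
#' @param eps_c_dot CE strain rate in 1/s (scalar or vector).
#' @param params A [muscle_tendon_params()].
#' @return Force scaling factor(s) in `[0, 1]`.
#' @export
force_velocity <- function(eps_c_dot, params) {
  stopifnot(inherits(params, "muscle_tendon_params"))
  v <- params$Lc0 * eps_c_dot
  out <- params$Vsh * (params$vmax + v) / (params$Vsh * params$vmax - v)
  out[eps_c_dot >= 0] <- 1
  out[v <= -params$vmax] <- 0
  out
}

#' Invert the concentric force-velocity relation
#'
#' Algebraic inverse of [force_velocity()] on its concentric branch: given a
#' force fraction `fv` in `(0, 1]`, returns the strain rate
#' `eps_dot = Vsh vmax (fv - 1) / (Lc0 (Vsh + fv))`, which maps `fv = 1` to
#' 0 and `fv -> 0+` to `-vmax / Lc0`. Needed because the fiber velocity must
#' be solved from the force balance at every integration step.
#'
#' @param fv Force fraction(s) in `(0, 1]`.
#' @param params A [muscle_tendon_params()].
#' @return CE strain rate(s) in 1/s (nonpositive).
#' @export
invert_force_velocity <- function(fv, params) {
  stopifnot(inherits(params, "muscle_tendon_params"))
  if (any(fv <= 0)) stop("'fv' must be > 0")
  if (any(fv > 1 + 1e-12)) stop("'fv' must be <= 1 on the concentric branch")
  params$Vsh * params$vmax * (fv - 1) / (params$Lc0 * (params$Vsh + fv))
}

#' Hill-type contraction dynamics under isometric whole-unit length
#'
#' Integrates the Hill-type contractile element in series with the linear
#' tendon, holding the whole muscle-tendon length fixed at
#' `Lc0 cos(phi) + Lt0`. At each step the tendon stretch gives the tendon
#' force `Ft = kt (Lt - Lt0)` (clipped at zero: a slack tendon carries no
#' load), the force balance `Ft = Fc cos(phi)` with
#' `Fc = a fl(eps) fv Fm` is solved for the force-velocity fraction `fv`,
#' `fv` is clamped to `[fv_floor, 1]` (only concentric shortening is
#' modeled; the upper clamp freezes the CE instead of lengthening it, and
#' the floor keeps the algebraic inversion away from its pole), the strain
#' rate follows from [invert_force_velocity()], and the strain is advanced
#' with a fixed-step fourth-order Runge-Kutta scheme with the activation
#' held constant within a step.
#'
#' The reported force trace is the contractile-element force of the Hill
#' relation, `Fc = a fl(eps) fv Fm`, which coincides with the tendon-borne
#' force `Ft / cos(phi)` whenever the clamp is not engaged.
#'
#' @param a Muscle activation in `[0, 1]` as a [uniform_series()].
#' @param params A [muscle_tendon_params()].
#' @param dt_int Integration step in seconds (default 1 ms); when the input
#'   sampling is finer than `dt_int` the input rate is used directly.
#' @param eps_limit Diagnostic bound on `|eps_c|` (default 0.5).
#' @param fv_floor Lower clamp on `fv` before inversion (default 1e-3).
#'
#' @return An object of class `hill_trace`: list with `Fc` and `eps_c`
#'   (both [uniform_series()] at the input rate) and
#'   `fv_clamped_fraction`, the fraction of integration steps at which
#'   either clamp engaged.
#' @export
simulate_hill <- function(a, params, dt_int = 1e-3,
                          eps_limit = 0.5, fv_floor = 1e-3) {
  stopifnot(is_uniform_series(a), inherits(params, "muscle_tendon_params"))
  av <- a$values
  if (any(!is.finite(av))) stop("activation contains NaN or Inf")
  if (min(av) < -1e-9 || max(av) > 1 + 1e-9) {
    stop("activation must lie in [0, 1]")
  }
  av <- pmin(pmax(av, 0), 1)
  n <- length(av)
  n_sub <- max(1L, as.integer(ceiling(a$dt / dt_int)))
  h <- a$dt / n_sub

  Fm <- params$Fm
  Lc0 <- params$Lc0
  kt <- params$kt
  b <- params$b
  cphi <- cos(params$phi)
  tiny <- 1e-12 * Fm

  clamped <- 0L
  total_steps <- 0L

  # strain rate for given strain and (frozen) activation; clamp bookkeeping
  # is done once per step at the step's initial state
  deriv <- function(eps, ak) {
    ft <- max(-kt * Lc0 * eps * cphi, 0)
    drive <- ak * force_length(eps, b) * Fm * cphi
    if (drive < tiny) {
      return(0)
    }
    fv_req <- ft / drive
    fv_used <- min(max(fv_req, fv_floor), 1)
    invert_force_velocity(fv_used, params)
  }

  eps <- 0
  Fc <- numeric(n)
  eps_tr <- numeric(n)
  for (k in seq_len(n)) {
    ak <- av[k]
    for (s in seq_len(n_sub)) {
      # clamp engagement flag at the current state
      ft0 <- max(-kt * Lc0 * eps * cphi, 0)
      drive0 <- ak * force_length(eps, b) * Fm * cphi
      if (drive0 >= tiny) {
        fv_req0 <- ft0 / drive0
        if (fv_req0 > 1 || fv_req0 < fv_floor) clamped <- clamped + 1L
      }
      total_steps <- total_steps + 1L

      k1 <- deriv(eps, ak)
      k2 <- deriv(eps + h / 2 * k1, ak)
      k3 <- deriv(eps + h / 2 * k2, ak)
      k4 <- deriv(eps + h * k3, ak)
      eps <- eps + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (abs(eps) > eps_limit) {
        stop(sprintf(
          "CE strain |%.4f| exceeded the physical limit %.2f at sample %d",
          eps, eps_limit, k
        ))
      }
    }
    ft <- max(-kt * Lc0 * eps * cphi, 0)
    drive <- ak * force_length(eps, b) * Fm * cphi
    fv_used <- if (drive < tiny) 0 else min(max(ft / drive, fv_floor), 1)
    Fc[k] <- ak * force_length(eps, b) * fv_used * Fm
    eps_tr[k] <- eps
  }

  structure(
    list(
      Fc = series_like(a, Fc),
      eps_c = series_like(a, eps_tr),
      fv_clamped_fraction = clamped / total_steps
    ),
    class = "hill_trace"
  )
}

#' @export
print.hill_trace <- function(x, ...) {
  cat(sprintf(
    "<hill_trace> %d samples, peak Fc = %.2f N, final eps_c = %.4f, fv clamped %.1f%% of steps\n",
    length(x$Fc), max(x$Fc$values), x$eps_c$values[length(x$eps_c)],
    100 * x$fv_clamped_fraction
  ))
  invisible(x)
}

#' Isometric Hill steady-state equilibrium
#'
#' Independent scalar root-finder for the steady state of [simulate_hill()]
#' under constant activation: solves the static force balance
#' `kt Lc0 (-eps) = a Fm fl(eps)` for the equilibrium strain (the tendon
#' force equals the isometric CE force rotated onto the tendon axis, with
#' `fv = 1`). Used as an oracle in the test-suite and available for quick
#' steady-state predictions.
#'
#' @param a Constant activation level in `(0, 1]`.
#' @param params A [muscle_tendon_params()].
#' @return List with `eps_c` (equilibrium strain, <= 0) and `Fc`
#'   (equilibrium CE force in N).
#' @export
hill_equilibrium <- function(a, params) {
  stopifnot(inherits(params, "muscle_tendon_params"))
  if (a < 0 || a > 1) stop("'a' must lie in [0, 1]")
  if (a == 0) {
    return(list(eps_c = 0, Fc = 0))
  }
  g <- function(eps) -params$kt * params$Lc0 * eps -
    a * params$Fm * force_length(eps, params$b)
  lower <- -a * params$Fm / (params$kt * params$Lc0) - 1e-9
  root <- stats::uniroot(g, lower = lower, upper = 0, tol = 1e-14)$root
  list(eps_c = root, Fc = a * params$Fm * force_length(root, params$b))
}
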