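#' Grid for the cross-bridge distribution solver
#'
#' Discretization of the normalized bond-length axis `y` (myosin-head /
#' actin-site distance divided by the maximum myosin-spring elongation `h`)
#' for the two-state attachment/detachment transport equation. Attachment is
#' possible only for `y` in `[0, 1]`; the grid must extend beyond that
#' window so that attached bridges transported out of it remain on the grid.
#' Cell centers are used so that the attachment window covers a whole number
#' of cells when `(y_max - y_min) / ny` divides 1.
#'
#' The sarcomere constants (`h`, rest length `S0`, single-population
#' stiffness `k0`, motor-unit count `N`) are never needed individually: the
#' solver only uses the aggregate transport gain `S0 / h` and the
#' macroscopic scales `km0 = S0 N k0 / Lc0` and `Fm = N k0 h / 2`, which it
#' takes from the accompanying [physio_params()]. Consistency of those
#' aggregates fixes `S0 / h = km0 Lc0 / (2 Fm)`.
#'
#' @param ny Number of grid cells (default 400).
#' @param y_min,y_max Grid extent (defaults -0.5 and 1.5).
#' @return An object of class `huxley_grid` with fields `y` (cell centers),
#'   `dy`, and the window mask `in_window`.
#' @export
huxley_grid <- function(ny = 400, y_min = -0.5, y_max = 1.5) {
  if (ny < 10) stop("'ny' must be at least 10")
  if (y_min >= 0 || y_max <= 1) {
    stop("the grid must contain the attachment window [0, 1] strictly")
  }
  dy <- (y_max - y_min) / ny
  y <- y_min + (seq_len(ny) - 0.5) * dy
  structure(
    list(y = y, dy = dy, ny = as.integer(ny),
         in_window = y > 0 & y < 1),
    class = "huxley_grid"
  )
}

#' Cross-bridge distribution solver (moment oracle)
#'
#' Integrates the two-state Huxley transport equation for the attached
#' fraction `n(y, t)` on the bond-length axis,
#' `dn/dt + (S0/h) eps_c_dot dn/dy = f (1 - n) - g n`,
#' with attachment rate `f = alpha Uc fl(eps_c) Pi_c` on the window
#' `y in [0, 1]` (zero outside) and detachment `g` chosen so that the total
#' rate is bond-length independent: `f + g = u + |eps_c_dot|` everywhere.
#' The numerical scheme is operator splitting per step: an exact exponential
#' relaxation for the reaction part followed by first-order upwind
#' transport. Because the total rate does not depend on `y`, the first two
#' moments of the solution obey closed ordinary differential equations; this
#' solver therefore serves as an independent oracle for
#' [simulate_physio()] (the agreement is exact up to discretization, with
#' no closure approximation).
#'
#' Outputs are reported at the muscle scale: `ks(t) = km0 * integral(n) dy`
#' and `Fs(t) = 2 Fm * integral(y n) dy`, so they are directly comparable
#' with the `kc` and `Fc` traces of [simulate_physio()] under the same
#' drive and prescribed strain-rate history.
#'
#' @param drive A `chemical_drive` sampled at the integration step.
#' @param eps_c_dot Prescribed CE strain rate, a [uniform_series()] on the
#'   drive's time base or a single number.
#' @param grid A [huxley_grid()].
#' @param params A [physio_params()].
#' @param alpha Recruitment ratio (single number, default 1).
#' @param eps_c0 Initial CE strain (default 0; trials start at rest).
#'
#' @return List with `ks` and `Fs` ([uniform_series()], N/m and N) and the
#'   final distribution `n`.
#' @export
huxley_pde_moments <- function(drive, eps_c_dot, grid, params,
                               alpha = 1, eps_c0 = 0) {
  stopifnot(inherits(drive, "chemical_drive"),
            inherits(grid, "huxley_grid"),
            inherits(params, "physio_params"))
  pi_v <- drive$pi_c$values
  u_v <- drive$u$values
  n_t <- length(pi_v)
  dt <- drive$pi_c$dt
  eps_dot_v <- if (is_uniform_series(eps_c_dot)) {
    check_same_time_base(drive$pi_c, eps_c_dot, "'eps_c_dot' and the drive")
    eps_c_dot$values
  } else {
    rep(as.numeric(eps_c_dot), n_t)
  }

  s0_over_h <- params$km0 * params$Lc0 / (2 * params$Fm)
  courant_max <- max(abs(eps_dot_v)) * s0_over_h * dt / grid$dy
  if (courant_max > 1) {
    stop(sprintf(
      "CFL condition violated (Courant number %.2f > 1); use a finer time step or coarser grid",
      courant_max
    ))
  }

  eps_c <- eps_c0 + cumsum(c(0, eps_dot_v[-n_t])) * dt

  n <- numeric(grid$ny)
  win <- grid$in_window
  y <- grid$y
  dy <- grid$dy
  ks <- numeric(n_t)
  Fs <- numeric(n_t)

  for (k in seq_len(n_t)) {
    # reaction substep: exact exponential relaxation per cell
    gtot <- u_v[k] + abs(eps_dot_v[k])
    f <- numeric(grid$ny)
    if (pi_v[k] == 1) {
      f[win] <- alpha * params$Uc * force_length(eps_c[k], params$b)
    }
    n_ss <- f / gtot
    n <- n_ss + (n - n_ss) * exp(-gtot * dt)

    # transport substep: first-order upwind, zero inflow at the boundary
    c_y <- s0_over_h * eps_dot_v[k]
    nu <- c_y * dt / dy
    if (nu > 0) {
      n <- n - nu * (n - c(0, n[-grid$ny]))
    } else if (nu < 0) {
      n <- n - nu * (c(n[-1], 0) - n)
    }

    # moments after the step, i.e. the state at the end of sample k
    # (matching the trace convention of simulate_physio)
    ks[k] <- params$km0 * sum(n) * dy
    Fs[k] <- 2 * params$Fm * sum(y * n) * dy
  }

  list(
    ks = series_like(drive$pi_c, ks),
    Fs = series_like(drive$pi_c, Fs),
    n = n
  )
}
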