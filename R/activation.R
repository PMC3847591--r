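#' Activation dynamics parameters
#'
#' Parameters of the delayed second-order recursion that turns the normalized
#' EMG envelope `e(t)` into neural activation `p(t)`, plus the nonlinear
#' shape factor `A` used by the nonlinear variant of the Hill model.
#'
#' The recursion is `p(k) = gamma * e(k - d) - beta1 * p(k - 1) - beta2 *
#' p(k - 2)` with `beta1 = C1 + C2`, `beta2 = C1 * C2`. Stability requires
#' `|C1| < 1` and `|C2| < 1`, and unit DC gain is enforced by `gamma = 1 +
#' beta1 + beta2`. The defaults `C1 = C2 = -0.5` give a critically damped
#' discrete twitch (double real pole at `z = 0.5`); the electromechanical
#' delay defaults to 40 ms, a typical value for the triceps surae, and is
#' rounded to the nearest whole sample at use.
#'
#' @param C1,C2 Recursion roots, each with modulus < 1.
#' @param d_s Electromechanical delay in seconds (>= 0).
#' @param A Nonlinear shape factor in `[-3, 0)`; `A = 0` selects the linear
#'   limit where muscle activation equals neural activation. `A = -3` is
#'   strongly exponential.
#'
#' @return An object of class `activation_params` with derived fields
#'   `beta1`, `beta2`, `gamma`.
#' @export
activation_params <- function(C1 = -0.5, C2 = -0.5, d_s = 0.040, A = 0) {
  if (abs(C1) >= 1 || abs(C2) >= 1) {
    stop("stability requires |C1| < 1 and |C2| < 1")
  }
  if (!is.finite(d_s) || d_s < 0) stop("'d_s' must be a nonnegative delay")
  if (!is.finite(A) || A < -3 || A > 0) {
    stop("'A' must lie in [-3, 0] (0 = linear limit)")
  }
  beta1 <- C1 + C2
  beta2 <- C1 * C2
  gamma <- 1 + beta1 + beta2
  structure(
    list(
      C1 = C1, C2 = C2, d_s = d_s, A = A,
      beta1 = beta1, beta2 = beta2, gamma = gamma
    ),
    class = "activation_params"
  )
}

#' Neural activation from the EMG envelope
#'
#' Applies the delayed second-order recursion `p(k) = gamma * e(k - d) -
#' beta1 * p(k - 1) - beta2 * p(k - 2)` with zero initial history
#' (`p = 0` and `e = 0` before the first sample). Because `gamma - beta1 -
#' beta2 = 1` the filter has unit DC gain, so a constant input converges to
#' itself. The recursion is linear; it models the twitch-like lag between
#' the electrical and the mechanical event.
#'
#' @param e Normalized EMG envelope as a [uniform_series()]; values are
#'   expected in `[0, 1]` (a warning is issued otherwise).
#' @param params An [activation_params()].
#' @return Neural activation `p(t)` as a [uniform_series()].
#' @export
neural_activation <- function(e, params) {
  stopifnot(is_uniform_series(e), inherits(params, "activation_params"))
  v <- e$values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    warning("envelope values outside [0, 1]; is the input MVC-normalized?")
  }
  d <- as.integer(round(params$d_s / e$dt))
  n <- length(v)
  p <- numeric(n)
  g <- params$gamma
  b1 <- params$beta1
  b2 <- params$beta2
  p1 <- 0
  p2 <- 0
  for (k in seq_len(n)) {
    ek <- if (k > d) v[k - d] else 0
    pk <- g * ek - b1 * p1 - b2 * p2
    p2 <- p1
    p1 <- pk
    p[k] <- pk
  }
  series_like(e, p)
}

#' Nonlinear muscle activation
#'
#' Maps neural activation `p` to muscle activation `a` through the
#' exponential shaping `a = (exp(A p) - 1) / (exp(A) - 1)`, which amplifies
#' low activation levels for `A < 0` (the documented mismatch of the linear
#' Hill model is largest at low forces). Endpoints are preserved (`a(0) = 0`,
#' `a(1) = 1`) and the map is strictly increasing; `A = 0` is handled as the
#' linear limit `a = p`.
#'
#' @param p Neural activation in `[0, 1]` as a [uniform_series()].
#' @param A Shape factor in `[-3, 0]`; 0 means linear.
#' @param tol Tolerance on the `[0, 1]` domain check.
#' @return Muscle activation `a(t)` as a [uniform_series()], values in
#'   `[0, 1]`.
#' @export
muscle_activation <- function(p, A, tol = 1e-6) {
  stopifnot(is_uniform_series(p))
  if (!is.finite(A) || A < -3 || A > 0) {
    stop("'A' must lie in [-3, 0] (0 = linear limit)")
  }
  v <- p$values
  if (min(v) < -tol || max(v) > 1 + tol) {
    stop("neural activation must lie in [0, 1]")
  }
  v <- pmin(pmax(v, 0), 1)
  if (A == 0) {
    return(series_like(p, v))
  }
  series_like(p, (exp(A * v) - 1) / (exp(A) - 1))
}
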