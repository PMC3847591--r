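#' Uniformly sampled time series
#'
#' The common carrier for every signal handled by the package: raw EMG,
#' rectified EMG, envelopes, neural and muscle activation, chemical input,
#' contractile force, active stiffness, strain and joint torque. A
#' `uniform_series` stores the sample values together with the sampling
#' interval `dt` and the time of the first sample `t0`; sample `k`
#' (1-based) sits at time `t0 + (k - 1) * dt`.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param dt Sampling interval in seconds (`dt > 0`).
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `uniform_series`.
#' @examples
#' x <- uniform_series(sin(2 * pi * 5 * seq(0, 1, by = 1 / 256)), dt = 1 / 256)
#' length(x)
#' head(time_points(x))
#' @export
uniform_series <- function(values, dt, t0 = 0) {
  if (!is.numeric(values) || length(values) < 1L) {
    stop("'values' must be a numeric vector with at least one sample")
  }
  if (!all(is.finite(values))) {
    stop("'values' contains non-finite samples")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number (seconds per sample)")
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("'t0' must be a single finite number (seconds)")
  }
  structure(
    list(values = as.numeric(values), dt = as.numeric(dt), t0 = as.numeric(t0)),
    class = "uniform_series"
  )
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#'
#' @param x A [uniform_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
time_points <- function(x) {
  stopifnot(is_uniform_series(x))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Test for the uniform series class
#' @param x Any object.
#' @return `TRUE` if `x` is a `uniform_series`.
#' @export
is_uniform_series <- function(x) inherits(x, "uniform_series")

#' @export
print.uniform_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<uniform_series> %d samples, dt = %g s (fs = %g Hz), t = [%g, %g] s\n",
    n, x$dt, 1 / x$dt, x$t0, x$t0 + (n - 1) * x$dt
  ))
  cat(sprintf(
    "  range [%g, %g]\n", min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
as.data.frame.uniform_series <- function(x, ...) {
  data.frame(time_s = time_points(x), value = x$values)
}

# Replace the values of a series, keeping its time base.
series_like <- function(template, values) {
  uniform_series(values, dt = template$dt, t0 = template$t0)
}

# Error unless two series share dt, t0 and length.
check_same_time_base <- function(x, y, what = "series") {
  if (length(x$values) != length(y$values) ||
      abs(x$dt - y$dt) > 1e-12 * x$dt ||
      abs(x$t0 - y$t0) > 1e-9) {
    stop(sprintf("%s must share the same time base (dt, t0, length)", what))
  }
  invisible(TRUE)
}
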