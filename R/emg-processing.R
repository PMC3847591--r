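#' Envelope-extraction configuration
#'
#' Parameters for the EMG conditioning chain: high-pass filtering to remove
#' motion artifacts, rectification, envelope extraction by zero-lag low-pass
#' filtering (or, alternatively, a moving-average window), and normalization
#' to the peak of a maximum voluntary contraction (MVC) trial.
#'
#' The stated filter orders refer to the *effective* (net) magnitude order of
#' the zero-lag filter: an order-4 zero-lag high-pass is realized as a
#' forward-backward pass of an order-2 Butterworth design, so the magnitude
#' response is the squared order-2 response and the phase is identically zero.
#'
#' @param hp_cutoff High-pass cutoff in Hz (artifact removal), default 30.
#' @param hp_order Effective high-pass order (even for zero-lag), default 4.
#' @param lp_cutoff Low-pass (envelope) cutoff in Hz, default 2; the usual
#'   working range is 2 Hz for slow tasks up to 6 Hz for fast tasks.
#' @param lp_order Effective low-pass order (even for zero-lag), default 2.
#' @param mav_window Optional moving-average window length in seconds
#'   (0.25-0.5 s is customary). When given it replaces the low-pass step.
#' @param mvc_peak Optional MVC-envelope peak used for normalization, in the
#'   units of the rectified EMG. Must be positive when supplied.
#'
#' @return An object of class `envelope_config`.
#' @export
envelope_config <- function(hp_cutoff = 30, hp_order = 4,
                            lp_cutoff = 2, lp_order = 2,
                            mav_window = NULL, mvc_peak = NULL) {
  if (lp_cutoff <= 0 || hp_cutoff <= 0 || lp_cutoff >= hp_cutoff) {
    stop("cutoffs must satisfy 0 < lp_cutoff < hp_cutoff")
  }
  if (hp_order < 1 || lp_order < 1) stop("filter orders must be >= 1")
  if (!is.null(mav_window) && (!is.finite(mav_window) || mav_window <= 0)) {
    stop("'mav_window' must be a positive duration in seconds")
  }
  if (!is.null(mvc_peak) && (!is.finite(mvc_peak) || mvc_peak <= 0)) {
    stop("'mvc_peak' must be > 0")
  }
  structure(
    list(
      hp_cutoff = hp_cutoff, hp_order = hp_order,
      lp_cutoff = lp_cutoff, lp_order = lp_order,
      mav_window = mav_window, mvc_peak = mvc_peak
    ),
    class = "envelope_config"
  )
}

# Odd ("mirror") reflection padding used to suppress the startup transient of
# the forward-backward filter on short bursts.
reflect_pad <- function(v, pad) {
  n <- length(v)
  front <- 2 * v[1] - v[seq(pad + 1, 2)]
  back <- 2 * v[n] - v[seq(n - 1, n - pad)]
  c(front, v, back)
}

# One causal pass of an ARMA filter started in its DC steady state for the
# first sample (direct-form-I history of past inputs/outputs), so that a
# constant signal passes through with exactly the DC gain and no transient.
filter_steady <- function(bf, v) {
  b <- bf$b
  a <- bf$a
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(
    bf, v,
    init.x = rep(v[1], length(b) - 1),
    init.y = rep(v[1] * dc, length(a) - 1)
  ))
}

#' Zero-lag Butterworth filter
#'
#' Applies a Butterworth filter with exactly zero phase shift by running the
#' filter forward and then backward over the signal (with odd-reflection
#' padding of three times the effective order at each end). The `order`
#' argument is the effective order of the net magnitude response, so the
#' underlying single-pass design has order `order / 2`; at the cutoff the net
#' amplitude response is the squared single-pass response, i.e. 1/2 instead
#' of 1/sqrt(2).
#'
#' @param x A [uniform_series()].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param order Effective filter order (must be even when `zero_lag = TRUE`).
#' @param kind `"high"` or `"low"`.
#' @param zero_lag If `TRUE` (default) use the forward-backward zero-phase
#'   scheme; if `FALSE` apply a single forward pass of an order-`order`
#'   design (for sensitivity studies; this pass has phase lag).
#'
#' @return Filtered [uniform_series()] of the same length and time base.
#' @export
zero_lag_butterworth <- function(x, cutoff, order,
                                 kind = c("high", "low"), zero_lag = TRUE) {
  stopifnot(is_uniform_series(x))
  kind <- match.arg(kind)
  nyquist <- 1 / (2 * x$dt)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyquist) {
    stop(sprintf(
      "cutoff must lie in (0, Nyquist = %g Hz), got %g Hz", nyquist, cutoff
    ))
  }
  if (zero_lag && order %% 2 != 0) {
    stop("zero-lag filtering needs an even effective 'order'")
  }
  pad <- 3L * as.integer(order)
  if (length(x$values) < pad + 1L) {
    stop(sprintf(
      "series too short for filtering: need at least %d samples, got %d",
      pad + 1L, length(x$values)
    ))
  }
  design_order <- if (zero_lag) order / 2 else order
  bf <- signal::butter(design_order, W = cutoff / nyquist, type = kind)
  v <- reflect_pad(x$values, pad)
  v <- filter_steady(bf, v)
  if (zero_lag) {
    v <- rev(filter_steady(bf, rev(v)))
  }
  v <- v[seq(pad + 1L, pad + length(x$values))]
  series_like(x, v)
}

#' Full-wave rectification
#'
#' @param x A [uniform_series()].
#' @return The elementwise absolute value as a [uniform_series()].
#' @export
rectify <- function(x) {
  stopifnot(is_uniform_series(x))
  series_like(x, abs(x$values))
}

# Centered moving average whose window shrinks to the valid range at the
# edges, so output stays within [min, max] of the input.
moving_average_shrink <- function(v, w) {
  n <- length(v)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' EMG envelope extraction
#'
#' Extracts the linear envelope of rectified EMG. By default a zero-lag
#' low-pass Butterworth at `cfg$lp_cutoff` is applied; if `cfg$mav_window`
#' is set, a centered moving average (MAV) over `round(mav_window / dt)`
#' samples is used instead, with the window shrinking to the valid range at
#' the series edges.
#'
#' @param x_rectified Rectified (nonnegative) EMG as a [uniform_series()].
#' @param cfg An [envelope_config()].
#' @return The envelope as a [uniform_series()].
#' @export
emg_envelope <- function(x_rectified, cfg) {
  stopifnot(is_uniform_series(x_rectified), inherits(cfg, "envelope_config"))
  if (any(x_rectified$values < 0)) {
    stop("'x_rectified' must be nonnegative; call rectify() first")
  }
  if (!is.null(cfg$mav_window)) {
    w <- as.integer(round(cfg$mav_window / x_rectified$dt))
    if (w < 1L) {
      stop("'mav_window' is shorter than one sample at this sampling rate")
    }
    series_like(x_rectified, moving_average_shrink(x_rectified$values, w))
  } else {
    zero_lag_butterworth(x_rectified, cfg$lp_cutoff, cfg$lp_order, "low")
  }
}

#' Normalize a series by an MVC peak
#'
#' Divides the series by the peak value of the processed maximum voluntary
#' contraction (MVC) trial, so that an MVC-trial envelope normalized by its
#' own peak has maximum exactly 1.
#'
#' @param x A [uniform_series()].
#' @param mvc_peak Positive peak value (same units as `x`).
#' @return Normalized [uniform_series()].
#' @export
normalize_mvc <- function(x, mvc_peak) {
  stopifnot(is_uniform_series(x))
  if (!is.numeric(mvc_peak) || length(mvc_peak) != 1L ||
      !is.finite(mvc_peak) || mvc_peak <= 0) {
    stop("'mvc_peak' must be a single positive number")
  }
  series_like(x, x$values / mvc_peak)
}

#' Full EMG conditioning chain
#'
#' Runs the four conditioning steps in order: zero-lag high-pass (artifact
#' removal), full-wave rectification, envelope extraction (zero-lag low-pass
#' or moving average) and, when `cfg$mvc_peak` is set, normalization to the
#' MVC peak.
#'
#' @param x Raw EMG as a [uniform_series()].
#' @param cfg An [envelope_config()].
#' @return The processed envelope `e(t)` as a [uniform_series()].
#' @export
process_emg <- function(x, cfg) {
  stopifnot(is_uniform_series(x), inherits(cfg, "envelope_config"))
  env <- emg_envelope(
    rectify(zero_lag_butterworth(x, cfg$hp_cutoff, cfg$hp_order, "high")),
    cfg
  )
  if (!is.null(cfg$mvc_peak)) env <- normalize_mvc(env, cfg$mvc_peak)
  env
}
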