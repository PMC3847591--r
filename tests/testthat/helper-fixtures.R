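# Shared helpers for the test-suite. All fixtures are built in code.

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(a^2))

const_series <- function(value, n = 256, dt = 1 / 256) {
  uniform_series(rep(value, n), dt = dt)
}

sine_series <- function(freq, fs = 256, duration = 4, amplitude = 1) {
  t <- seq(0, duration, by = 1 / fs)
  uniform_series(amplitude * sin(2 * pi * freq * t), dt = 1 / fs)
}

# Complex frequency response of a discrete ARMA filter at frequency f (Hz),
# evaluated directly from the coefficients -- independent of signal::filter.
arma_response <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
  num <- sum(bf$b * z)
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$a) - 1))
  num / sum(bf$a * z)
}

# Amplitude of a (quasi-)steady sinusoid: peak over the central half.
central_amplitude <- function(x) {
  n <- length(x$values)
  max(abs(x$values[seq(round(n / 4), round(3 * n / 4))]))
}

# Simple two-burst command at a given sampling rate (forward-model tests).
burst_command <- function(duration, level = 0.6, fs = 512,
                          settle = 2.5) {
  segs <- data.frame(
    label = c("rest", "burst", "rest"),
    duration = c(0.5, duration, settle),
    level = c(0, level, 0),
    ramp = c(0, 0.02, 0.02)
  )
  build_command(segs, fs)$command
}
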