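# Shared fixtures: standard probe/phantom builders and signal constructions
# used across the estimator tests.

std_indenter <- function() indenter(10e-3)

std_phantom <- function(E = 10e3, h = 30e-3, v = 1540, beta = 0, ...) {
  tissue_phantom(h, v, E, stiffening_beta = beta, ...)
}

force_load <- function(P) load_step(sprintf("%gN", P), applied_force = P)

# Band-limited Gaussian random signal, peak-normalized. Passband in units
# of the sampling rate.
bandlimited_signal <- function(n, lo = 0.02, hi = 0.2) {
  X <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / n
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / max(abs(x))
}

# Exact (possibly fractional) delay of d samples via FFT phase ramp;
# the independent construction used by the shift-recovery oracle.
delay_samples <- function(x, d) {
  n <- length(x)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * k * d / n), inverse = TRUE) / n)
}

# Integer circular-free roll with zero padding (same length).
roll_samples <- function(x, k) {
  n <- length(x)
  if (k > 0) c(numeric(k), x[seq_len(n - k)])
  else if (k < 0) c(x[(-k + 1):n], numeric(-k))
  else x
}
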