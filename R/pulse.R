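#' Transducer excitation pulse model
#'
#' Describes the emitted pulse as a Gaussian-windowed sinusoid (Gabor
#' pulse): a carrier at `center_frequency` under a Gaussian envelope whose
#' -6 dB spectral full width equals `fractional_bandwidth * center_frequency`.
#' The default 2 MHz carrier matches a low-frequency single-element probe
#' suited to centimetre-deep soft tissue.
#'
#' @param center_frequency Carrier frequency in Hz; must be positive.
#' @param fractional_bandwidth -6 dB bandwidth as a fraction of the carrier,
#'   in (0, 1].
#' @param amplitude Peak amplitude, arbitrary units; non-negative.
#' @return An object of class `pulse_model`.
#' @examples
#' pm <- pulse_model(2e6, 0.6, 1)
#' @export
pulse_model <- function(center_frequency = 2e6, fractional_bandwidth = 0.6,
                        amplitude = 1) {
  if (!is.numeric(center_frequency) || center_frequency <= 0)
    stop("`center_frequency` must be positive", call. = FALSE)
  if (!is.numeric(fractional_bandwidth) || fractional_bandwidth <= 0 ||
      fractional_bandwidth > 1)
    stop("`fractional_bandwidth` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("`amplitude` must be non-negative", call. = FALSE)
  structure(
    list(center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         amplitude = amplitude),
    class = "pulse_model"
  )
}

# Gaussian envelope sigma (seconds) giving the requested -6 dB width.
# exp(-2 pi^2 sigma^2 (df/2)^2) = 1/2  =>  sigma = sqrt(2 log 2) / (pi df)
pulse_sigma <- function(pulse) {
  df <- pulse$fractional_bandwidth * pulse$center_frequency
  sqrt(2 * log(2)) / (pi * df)
}

# Continuous-time Gabor pulse evaluated at arbitrary times (seconds),
# centred at t0. Used by the echo simulator for exact sub-sample placement.
gabor_eval <- function(t, t0, center_frequency, sigma, amplitude) {
  dt <- t - t0
  amplitude * exp(-dt^2 / (2 * sigma^2)) * cos(2 * pi * center_frequency * dt)
}

#' Sample the excitation pulse waveform
#'
#' Evaluates the Gabor pulse on a uniform grid (+/- 4 envelope standard
#' deviations about the centre), removes the residual DC component, and
#' rescales so the peak absolute sample equals the model amplitude.
#'
#' @param pulse A [pulse_model()].
#' @param sampling_rate Sampling rate in Hz; must be at least 10 times the
#'   carrier so sub-sample arrival shifts stay resolvable.
#' @return Numeric waveform with attributes `sampling_rate` and
#'   `center_index` (sample index of the envelope centre).
#' @examples
#' w <- make_pulse(pulse_model(2e6, 0.6, 1), 50e6)
#' max(abs(w)) # 1
#' @export
make_pulse <- function(pulse, sampling_rate) {
  stopifnot(inherits(pulse, "pulse_model"))
  if (!is.numeric(sampling_rate) || sampling_rate < 10 * pulse$center_frequency)
    stop("invalid configuration: `sampling_rate` must be >= 10 * center_frequency",
         call. = FALSE)
  sigma <- pulse_sigma(pulse)
  n_half <- ceiling(4 * sigma * sampling_rate)
  t <- (-n_half:n_half) / sampling_rate
  w <- gabor_eval(t, 0, pulse$center_frequency, sigma, pulse$amplitude)
  if (pulse$amplitude > 0) {
    w <- w - mean(w)
    w <- w * (pulse$amplitude / max(abs(w)))
  }
  attr(w, "sampling_rate") <- sampling_rate
  attr(w, "center_index") <- n_half + 1L
  w
}
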