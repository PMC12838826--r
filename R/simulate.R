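#' Simulate one A-mode echo signal under an indentation load
#'
#' One-dimensional two-interface echo model: the received signal is the
#' excitation pulse replicated at the probe-tissue surface (t = 0, fixed
#' amplitude) and at the compressed back interface, whose round-trip
#' arrival time is `t = 2 (h - w) / v` with `w` the quasi-static
#' deformation from [deform()]. The back echo amplitude is scaled by
#' frequency-linear attenuation, `10^(-alpha * d_cm * f0_MHz / 20)` over
#' the round-trip path `d_cm = 200 (h - w)`; attenuation never affects
#' timing. No multiple reflections or diffraction are modelled: the
#' analysis downstream only tracks one echo's arrival time.
#'
#' With `snr_db` set, additive white Gaussian noise is drawn from a local,
#' seeded RNG with RMS such that `20 log10(peak / RMS) = snr_db`, peak
#' being the clean signal's absolute maximum.
#'
#' @param phantom A [tissue_phantom()].
#' @param ind An [indenter()].
#' @param load A [load_step()].
#' @param pulse A [pulse_model()].
#' @param sampling_rate Sampling rate in Hz (>= 10x the carrier);
#'   default 50 MHz.
#' @param snr_db Peak-signal SNR in dB, or `NULL` for noise-free.
#' @param seed Integer seed for the noise draw.
#' @return An [ascan()]; duration covers the full round trip `2 h / v`.
#' @examples
#' ph <- tissue_phantom(30e-3, 1540, 10e3)
#' s <- simulate_ascan(ph, indenter(10e-3), load_step("0N", applied_force = 0),
#'                     pulse_model(), seed = 1)
#' @export
simulate_ascan <- function(phantom, ind, load, pulse = pulse_model(),
                           sampling_rate = 50e6, snr_db = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(ind, "indenter"),
            inherits(load, "load_step"), inherits(pulse, "pulse_model"))
  if (sampling_rate < 10 * pulse$center_frequency)
    stop("invalid configuration: `sampling_rate` must be >= 10 * center_frequency",
         call. = FALSE)
  st <- deform(phantom, ind, load)
  sigma <- pulse_sigma(pulse)
  f0 <- pulse$center_frequency
  t_back <- 2 * st$compressed_thickness_hi / phantom$sound_speed_v
  t_full <- 2 * phantom$thickness_h / phantom$sound_speed_v

  time_origin <- -4 * sigma
  t_end <- t_full + 6 * sigma
  n <- ceiling((t_end - time_origin) * sampling_rate) + 1L
  t <- time_origin + (seq_len(n) - 1L) / sampling_rate

  atten <- 10^(-phantom$attenuation_alpha * (200 * st$compressed_thickness_hi) *
                 (f0 / 1e6) / 20)
  clean <- gabor_eval(t, 0, f0, sigma, pulse$amplitude) +
    gabor_eval(t, t_back, f0, sigma, pulse$amplitude * atten)

  samples <- clean
  if (!is.null(snr_db)) {
    peak <- max(abs(clean))
    rms <- peak / 10^(snr_db / 20)
    noise <- with_seed(seed, rnorm(n, sd = rms))
    samples <- clean + noise
  }
  ascan(samples, sampling_rate = sampling_rate, time_origin = time_origin,
        load_label = load$label, seed = seed)
}

#' Simulate a stepped-load indentation sweep
#'
#' One A-scan per load step, in protocol order; the first step is the
#' baseline and must carry the lowest force. Per-signal noise seeds are
#' derived deterministically from the base seed and the load index, so a
#' sweep is bit-reproducible from its configuration.
#'
#' @inheritParams simulate_ascan
#' @param loads Non-empty list of [load_step()]s, baseline first.
#' @param seed Integer base seed.
#' @return List of [ascan()]s, one per load, order preserved.
#' @export
simulate_sweep <- function(phantom, ind, loads, pulse = pulse_model(),
                           sampling_rate = 50e6, snr_db = NULL, seed = NULL) {
  if (length(loads) == 0)
    stop("invalid protocol: `loads` must be non-empty", call. = FALSE)
  forces <- vapply(loads, resolve_force, numeric(1), ind = ind)
  if (forces[1] != min(forces))
    stop("invalid protocol: the first load must be the lowest (baseline)",
         call. = FALSE)
  lapply(seq_along(loads), function(i) {
    si <- if (is.null(seed)) NULL else (as.integer(seed) + i - 1L)
    simulate_ascan(phantom, ind, loads[[i]], pulse,
                   sampling_rate = sampling_rate, snr_db = snr_db, seed = si)
  })
}
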