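#' Analytic-signal envelope of an A-scan
#'
#' Magnitude of the analytic signal, computed by one-sided spectrum
#' doubling in the frequency domain: the envelope demodulates the carrier
#' so echo arrival shows as a smooth peak.
#'
#' @param x An [ascan()] or numeric vector of length >= 8 with finite
#'   samples.
#' @return Numeric envelope, same length as the input.
#' @export
envelope <- function(x) {
  s <- if (inherits(x, "ascan")) x$samples else x
  if (!is.numeric(s) || length(s) < 8)
    stop("invalid signal: need at least 8 samples", call. = FALSE)
  if (!all(is.finite(s)))
    stop("invalid signal: non-finite samples", call. = FALSE)
  n <- length(s)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(s) * h, inverse = TRUE) / n)
}

# 3-point parabolic refinement of a discrete peak; returns the fractional
# offset in (-0.5, 0.5] about index i, 0 at the boundary or on a flat top.
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(0)
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(d, 0.5), -0.5)
}

#' Envelope-peak arrival time within a window
#'
#' Finds the time of the envelope maximum inside `search_window`
#' (absolute signal time, seconds), refined by 3-point parabolic
#' interpolation around the discrete argmax. Ties at the discrete maximum
#' are broken toward the earliest sample; a window whose envelope is flat
#' (no unambiguous peak) is an error.
#'
#' @param x An [ascan()].
#' @param search_window Length-2 numeric `(t_min, t_max)` in s; `NULL`
#'   searches the full signal.
#' @return Arrival time in s, inside the window.
#' @export
peak_time <- function(x, search_window = NULL) {
  stopifnot(inherits(x, "ascan"))
  t <- ascan_times(x)
  if (is.null(search_window)) search_window <- range(t)
  idx <- which(t >= search_window[1] & t <= search_window[2])
  if (length(idx) == 0)
    stop("invalid window: no samples inside `search_window`", call. = FALSE)
  env <- envelope(x)
  ew <- env[idx]
  if (max(ew) == min(ew))
    stop("invalid window: flat envelope, no unambiguous peak", call. = FALSE)
  k <- idx[which.max(ew)]
  off <- parabolic_offset(env, k)
  res <- t[k] + off / x$sampling_rate
  min(max(res, search_window[1]), search_window[2])
}

#' Sub-sample delay between two signals by normalized cross-correlation
#'
#' Maximizes the normalized cross-correlation over lags within
#' `+/- max_lag`, refined by parabolic interpolation on the correlation
#' peak. A positive lag means `signal`'s content arrives later than
#' `reference`'s.
#'
#' @param reference,signal [ascan()]s with equal sampling rates.
#' @param max_lag Largest |lag| searched, in s; must be below half the
#'   common duration. Default: a quarter of the shorter signal.
#' @return Estimated delay in s.
#' @export
xcorr_delay <- function(reference, signal, max_lag = NULL) {
  stopifnot(inherits(reference, "ascan"), inherits(signal, "ascan"))
  if (abs(reference$sampling_rate - signal$sampling_rate) >
      1e-6 * reference$sampling_rate)
    stop("incompatible signals: sampling rates differ", call. = FALSE)
  fs <- reference$sampling_rate
  a <- reference$samples
  b <- signal$samples
  if (sum(a^2) == 0 || sum(b^2) == 0)
    stop("invalid signal: zero energy", call. = FALSE)
  n <- max(length(a), length(b))
  if (is.null(max_lag)) max_lag <- 0.25 * min(length(a), length(b)) / fs
  L <- floor(max_lag * fs)
  if (L < 1 || 2 * L >= n)
    stop("invalid `max_lag`: must allow at least one sample and be below half the duration",
         call. = FALSE)
  nfft <- 2^ceiling(log2(n + L + 1))
  A <- fft(c(a, numeric(nfft - length(a))))
  B <- fft(c(b, numeric(nfft - length(b))))
  r <- Re(fft(Conj(A) * B, inverse = TRUE) / nfft)
  # r[k + 1] holds lag k (mod nfft); assemble lags -L..L
  lags <- -L:L
  cc <- r[(lags %% nfft) + 1]
  cc <- cc / sqrt(sum(a^2) * sum(b^2))
  i <- which.max(cc)
  off <- parabolic_offset(cc, i)
  (lags[i] + off) / fs
}

#' ToF difference between a baseline and a loaded A-scan
#'
#' The stiffness proxy: `tau` is the advance of the back echo under load,
#' positive when the loaded echo arrives earlier (compression). Two
#' estimators are provided: `"xcorr"` (default; windowed normalized
#' cross-correlation, more noise-robust) and `"envelope_peak"` (difference
#' of [peak_time()]s). The search window defaults to the rear
#' three-quarters of the signal, `(t0 + 0.25 T, t0 + T)`, excluding the
#' surface echo.
#'
#' @param baseline,loaded [ascan()]s at the same sampling rate, baseline
#'   being the lower-load state.
#' @param method `"xcorr"` or `"envelope_peak"`.
#' @param search_window Length-2 numeric in s, or `NULL` for the default.
#' @return An object of class `tof_measurement`: `load_label`,
#'   `tof_difference_tau` (s), `method`, `uncertainty` (s or `NA`).
#' @examples
#' ph <- tissue_phantom(30e-3, 1540, 10e3)
#' ind <- indenter(10e-3)
#' b <- simulate_ascan(ph, ind, load_step("0N", applied_force = 0))
#' l <- simulate_ascan(ph, ind, load_step("1N", applied_force = 1))
#' tof_difference(b, l)
#' @export
tof_difference <- function(baseline, loaded,
                           method = c("xcorr", "envelope_peak"),
                           search_window = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(baseline, "ascan"), inherits(loaded, "ascan"))
  if (abs(baseline$sampling_rate - loaded$sampling_rate) >
      1e-6 * baseline$sampling_rate)
    stop("incompatible signals: sampling rates differ", call. = FALSE)
  if (is.null(search_window)) {
    dur <- length(baseline$samples) / baseline$sampling_rate
    search_window <- baseline$time_origin + c(0.25, 1) * dur
  }
  tau <- if (method == "envelope_peak") {
    peak_time(baseline, search_window) - peak_time(loaded, search_window)
  } else {
    # Coarse-to-fine: integer-sample pre-alignment by cross-correlating the
    # windowed envelopes (robust to noise, any compression depth), then a
    # small-lag correlation on the raw signals for sub-sample precision.
    fs <- baseline$sampling_rate
    tb <- ascan_times(baseline)
    idx <- which(tb >= search_window[1] & tb <= search_window[2])
    if (length(idx) < 8)
      stop("invalid window: too few samples for cross-correlation", call. = FALSE)
    idx <- idx[idx <= length(loaded$samples)]
    # box-filtering the envelope over ~a pulse width integrates the echo's
    # energy, so a lone noise spike cannot outvote it at the coarse stage
    width <- max(3L, round(0.5e-6 * fs))
    smooth <- function(e) {
      sm <- stats::filter(e, rep(1 / width, width), sides = 2)
      sm[is.na(sm)] <- 0
      as.numeric(sm)
    }
    coarse <- which.max(smooth(envelope(baseline)[idx])) -
      which.max(smooth(envelope(loaded)[idx]))
    y <- loaded$samples
    n <- length(y)
    y <- if (coarse > 0) c(numeric(coarse), y[seq_len(n - coarse)])
    else if (coarse < 0) c(y[(-coarse + 1):n], numeric(-coarse))
    else y
    ref_w <- ascan(baseline$samples[idx], fs)
    sig_w <- ascan(y[idx], fs)
    residual <- xcorr_delay(ref_w, sig_w,
                            max_lag = min(2e-6, (floor(length(idx) / 2) - 2) / fs))
    coarse / fs - residual
  }
  structure(
    list(load_label = loaded$load_label, tof_difference_tau = tau,
         method = method, uncertainty = NA_real_),
    class = "tof_measurement"
  )
}

#' Temporally align A-scans on their surface echo
#'
#' Each signal's surface echo is located as the first envelope peak above
#' `threshold_frac` of that signal's envelope maximum, then every signal
#' is shifted by a whole number of samples so its surface echo coincides
#' with the reference's. Used to remove couplant/standoff offsets before
#' comparing ToF differences across recordings.
#'
#' @param signals List of >= 2 [ascan()]s with a common sampling rate.
#' @param reference_index Index of the reference signal (left unshifted).
#' @param threshold_frac Detection threshold as a fraction of the global
#'   envelope maximum; default 0.5.
#' @return List with `shifts` (applied shift per signal, s; 0 for the
#'   reference), `reference_label`, and `signals` (shifted copies).
#' @export
align_signals <- function(signals, reference_index = 1, threshold_frac = 0.5) {
  if (length(signals) < 2)
    stop("need at least 2 signals to align", call. = FALSE)
  fs <- signals[[1]]$sampling_rate
  ok <- vapply(signals, function(s)
    abs(s$sampling_rate - fs) <= 1e-6 * fs, logical(1))
  if (!all(ok))
    stop("incompatible signals: sampling rates differ", call. = FALSE)

  surface_time <- function(s) {
    env <- envelope(s)
    thr <- threshold_frac * max(env)
    if (max(env) == 0)
      stop(sprintf("alignment failure: no surface echo found in '%s'",
                   s$load_label), call. = FALSE)
    i <- which(env >= thr)[1]
    while (i < length(env) && env[i + 1] > env[i]) i <- i + 1
    s$time_origin + (i - 1 + parabolic_offset(env, i)) / fs
  }

  times <- vapply(signals, surface_time, numeric(1))
  ref_t <- times[reference_index]
  k <- round((ref_t - times) * fs)  # samples to shift each signal by
  k[reference_index] <- 0L
  shifted <- lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    ki <- k[i]
    x <- s$samples
    n <- length(x)
    y <- if (ki > 0) c(numeric(ki), x[seq_len(n - ki)])
    else if (ki < 0) c(x[(-ki + 1):n], numeric(-ki))
    else x
    ascan(y, s$sampling_rate, s$time_origin, s$load_label, s$seed)
  })
  list(shifts = k / fs,
       reference_label = signals[[reference_index]]$load_label,
       signals = shifted)
}

#' ToF-difference table for a simulated or recorded sweep
#'
#' Computes tau for every loaded signal against the first (baseline)
#' signal of a sweep and returns a tidy table; the baseline row carries
#' tau = 0 by definition.
#'
#' @param ascans List of [ascan()]s, baseline first.
#' @param forces_N Optional numeric vector of forces (N) per signal, added
#'   as a column.
#' @inheritParams tof_difference
#' @return `data.frame` with columns `load_label`, `force_N` (if given),
#'   `tau_s`, `method`.
#' @export
tof_table <- function(ascans, forces_N = NULL,
                      method = c("xcorr", "envelope_peak"),
                      search_window = NULL) {
  method <- match.arg(method)
  if (length(ascans) < 1) stop("empty sweep", call. = FALSE)
  taus <- c(0, vapply(ascans[-1], function(s)
    tof_difference(ascans[[1]], s, method = method,
                   search_window = search_window)$tof_difference_tau,
    numeric(1)))
  out <- data.frame(
    load_label = vapply(ascans, function(s) s$load_label, character(1)),
    tau_s = taus, method = method, stringsAsFactors = FALSE)
  if (!is.null(forces_N)) out$force_N <- forces_N
  out[, c("load_label", intersect("force_N", names(out)), "tau_s", "method")]
}
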