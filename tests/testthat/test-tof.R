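test_that("envelope demodulates a Gabor pulse and is symmetric and bounded", {
  w <- make_pulse(pulse_model(2e6, 0.6, 1), 50e6)
  env <- envelope(w)
  expect_length(env, length(w))
  # envelope max within one sample of the window centre
  expect_lte(abs(which.max(env) - attr(w, "center_index")), 1)
  # envelope >= |signal| up to numerical tolerance
  expect_true(all(env >= abs(w) - 1e-9))
  expect_equal(envelope(-w), env, tolerance = 1e-12)
  expect_equal(envelope(numeric(16)), numeric(16))
  expect_error(envelope(c(1, NA, rep(0, 10))), "non-finite")
  expect_error(envelope(1:4), "at least 8")
})

test_that("peak_time refines to sub-sample accuracy and respects the window", {
  fs <- 50e6
  ph <- std_phantom()
  s <- simulate_ascan(ph, std_indenter(), force_load(0), sampling_rate = fs)
  t0 <- peak_time(s, c(30e-6, 45e-6))
  expect_lt(abs(t0 - 2 * 0.03 / 1540), 0.5 / fs)

  # shifting the whole signal by k samples shifts peak_time by k/fs
  for (k in c(-7L, 13L)) {
    sk <- ascan(roll_samples(s$samples, k), fs, s$time_origin)
    expect_lt(abs((peak_time(sk, c(30e-6, 45e-6)) - t0) - k / fs), 0.01 / fs)
  }

  flat <- ascan(numeric(64), fs)
  expect_error(peak_time(flat), "no unambiguous peak")
  expect_error(peak_time(s, c(1, 2)), "invalid window")
})

test_that("cross-correlation delay recovers integer shifts exactly", {
  fs <- 50e6
  # pulse embedded in quiet buffers so integer rolls move it losslessly
  base <- c(numeric(500), make_pulse(pulse_model(2e6, 0.6, 1), fs), numeric(500))
  ref <- ascan(base, fs)
  expect_equal(xcorr_delay(ref, ref), 0)
  for (k in c(-21L, -3L, 1L, 13L)) {
    shifted <- ascan(roll_samples(base, k), fs)
    expect_equal(xcorr_delay(ref, shifted, max_lag = 1e-6) * fs, k)
  }
})

test_that("cross-correlation delay recovers fractional shifts on band-limited signals", {
  fs <- 50e6
  set.seed(17)
  x <- bandlimited_signal(8192)
  ref <- ascan(x, fs)
  est <- xcorr_delay(ref, ascan(delay_samples(x, 0.3), fs), max_lag = 16 / fs)
  expect_lt(abs(est * fs - 0.3), 0.05)

  # randomized property: fractional shifts, noise-free and at 20 dB peak SNR
  errs <- vapply(1:40, function(i) {
    xi <- bandlimited_signal(8192)
    d <- stats::runif(1, -8, 8)
    y <- delay_samples(xi, d) + stats::rnorm(8192, sd = 0.1)
    xcorr_delay(ascan(xi, fs), ascan(y, fs), max_lag = 16 / fs) * fs - d
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("cross-correlation delay is antisymmetric and validates its inputs", {
  fs <- 50e6
  set.seed(5)
  x <- bandlimited_signal(4096)
  y <- delay_samples(x, 2.7)
  d_ab <- xcorr_delay(ascan(x, fs), ascan(y, fs), max_lag = 16 / fs)
  d_ba <- xcorr_delay(ascan(y, fs), ascan(x, fs), max_lag = 16 / fs)
  expect_equal(d_ab, -d_ba, tolerance = 0.05 / fs / abs(d_ab))

  expect_error(xcorr_delay(ascan(x, fs), ascan(y, 40e6)), "incompatible")
  expect_error(xcorr_delay(ascan(numeric(64), fs), ascan(y, fs)), "zero energy")
})

test_that("tof_difference matches the round-trip arithmetic for both estimators", {
  ind <- std_indenter()
  ph <- std_phantom(E = 10e3)
  P <- 2 * 0.01 * 10e3 * 1e-3 / 0.75 # w = 1 mm
  b <- simulate_ascan(ph, ind, force_load(0))
  l <- simulate_ascan(ph, ind, force_load(P))
  tau_expect <- 2 * 1e-3 / 1540

  taus <- vapply(c("xcorr", "envelope_peak"), function(m)
    tof_difference(b, l, method = m)$tof_difference_tau, numeric(1))
  expect_true(all(abs(taus - tau_expect) < 0.02e-6))
  # cross-method agreement within one sample period
  expect_lt(abs(taus[1] - taus[2]), 1 / b$sampling_rate)

  same <- tof_difference(b, b)
  expect_equal(same$tof_difference_tau, 0, tolerance = 1e-12)
  expect_equal(tof_difference(b, l, method = "xcorr")$method, "xcorr")
})

test_that("tau estimates stay stable under seeded noise at 20 dB SNR", {
  ind <- std_indenter()
  ph <- std_phantom(E = 10e3)
  taus <- vapply(1:60, function(s) {
    b <- simulate_ascan(ph, ind, force_load(0), snr_db = 20, seed = 2 * s)
    l <- simulate_ascan(ph, ind, force_load(1), snr_db = 20, seed = 2 * s + 1)
    tof_difference(b, l)$tof_difference_tau
  }, numeric(1))
  expect_lt(stats::sd(taus), 0.5e-6) # below one carrier period at 2 MHz
  expect_equal(mean(taus), 2 * 3.75e-3 / 1540, tolerance = 0.01)
})

test_that("alignment recovers inserted integer offsets and is idempotent", {
  fs <- 50e6
  ph <- std_phantom()
  s <- simulate_ascan(ph, std_indenter(), force_load(0))
  mk <- function(k) ascan(roll_samples(s$samples, k), fs, s$time_origin,
                          load_label = sprintf("off%+d", k))
  res <- align_signals(list(mk(0L), mk(5L), mk(-3L)))
  expect_equal(res$shifts * fs, c(0, -5, 3))
  expect_equal(res$reference_label, "off+0")

  again <- align_signals(res$signals)
  expect_true(all(abs(again$shifts * fs) <= 1))

  same <- align_signals(list(s, s, s))
  expect_equal(same$shifts, c(0, 0, 0))
  expect_error(align_signals(list(s)), "at least 2")
})
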