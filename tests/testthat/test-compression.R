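test_that("zero-phase bandpass keeps in-band tones and rejects out-of-band drift", {
  fs <- fix_fs
  t <- (0:2599) / fs
  tone3 <- sin(2 * pi * 3 * t)
  out <- bandpass_filter(tone3, fs)
  mid <- 400:2200                                  # avoid filter edge transients
  gain_db <- 20 * log10(max(abs(out[mid])) / max(abs(tone3[mid])))
  expect_gt(gain_db, -1)
  drift <- sin(2 * pi * 0.2 * t)
  out_lo <- bandpass_filter(drift, fs)
  expect_lt(20 * log10(max(abs(out_lo[mid]))), -20)
  tone10 <- sin(2 * pi * 10 * t)                   # one octave above the 5 MHz edge
  out_hi <- bandpass_filter(tone10, fs)
  expect_lt(20 * log10(max(abs(out_hi[mid]))), -20)
  expect_error(bandpass_filter(tone3, fs, 5, 1), class = "needletrack_filter_design")
})

test_that("bandpass filtering does not shift the compressed-envelope peak", {
  n <- round(40 * fix_fs)
  x <- placed_trace(fix_chirp, 18, fix_fs, n)
  i_raw <- which.max(pulse_compress(x, fix_chirp, fix_fs)$envelope)
  i_filt <- which.max(pulse_compress(bandpass_filter(x, fix_fs), fix_chirp, fix_fs)$envelope)
  expect_lte(abs(i_raw - i_filt), 1L)
})

test_that("pulse compression peaks at the arrival of the excitation start", {
  n <- round(40 * fix_fs)
  # autocorrelation: template at lag 0
  x0 <- c(fix_chirp, numeric(n - length(fix_chirp)))
  ct0 <- pulse_compress(x0, fix_chirp, fix_fs)
  expect_equal(ct0$lag_axis[which.max(ct0$envelope)], 0)
  # known fractional delay built with an independent sinc-interpolation oracle
  tau <- 13.50
  xf <- sinc_delay(fix_chirp, tau, fix_fs, n)
  ctf <- pulse_compress(xf, fix_chirp, fix_fs)
  expect_equal(ctf$lag_axis[which.max(ctf$envelope)], tau, tolerance = 0.02)
  expect_error(pulse_compress(numeric(0), fix_chirp, fix_fs),
               class = "needletrack_invalid_signal")
  expect_error(pulse_compress(fix_chirp[1:10], fix_chirp, fix_fs),
               class = "needletrack_invalid_signal")
})

test_that("compressed peak amplitude approximates the received copy amplitude", {
  n <- round(30 * fix_fs)
  x <- placed_trace(fix_chirp, 12, fix_fs, n, amp = 0.37)
  ct <- pulse_compress(x, fix_chirp, fix_fs)
  expect_equal(max(ct$envelope), 0.37, tolerance = 0.01)
})

test_that("envelope detection matches analytic forms", {
  fs <- fix_fs
  t <- (0:999) / fs
  tone <- 0.8 * sin(2 * pi * 3 * t)
  env <- signal_envelope(tone)
  expect_equal(stats::median(env[100:900]), 0.8, tolerance = 0.02)
  burst <- make_toneburst(toneburst_spec())
  envb <- signal_envelope(burst)
  g <- exp(-((seq_along(burst) - (length(burst) + 1) / 2) / fs)^2 /
             (2 * ((4 / 3) / 2.355)^2))
  expect_lt(max(abs(envb - g)), 0.08)
  # compressed chirp envelope is unimodal above -6 dB
  ct <- pulse_compress(placed_trace(fix_chirp, 15, fs, round(40 * fs)), fix_chirp, fs)
  supra <- which(ct$envelope >= max(ct$envelope) / 2)
  expect_true(all(diff(supra) == 1L))
})

test_that("the transmitted chirp is the best-matched template", {
  n <- round(40 * fix_fs)
  x <- placed_trace(fix_chirp, 18, fix_fs, n)
  peak_for <- function(tmpl) max(pulse_compress(x, tmpl, fix_fs)$envelope *
                                   sqrt(sum(tmpl^2)))  # undo energy normalization
  expect_gt(peak_for(fix_chirp), peak_for(rev(fix_chirp)))
  expect_gt(peak_for(fix_chirp), peak_for(make_toneburst(toneburst_spec())))
})

test_that("compression is linear: two separated arrivals give two peaks", {
  n <- round(50 * fix_fs)
  x <- placed_trace(fix_chirp, 12, fix_fs, n) + placed_trace(fix_chirp, 30, fix_fs, n, amp = 0.7)
  ct <- pulse_compress(x, fix_chirp, fix_fs)
  i1 <- which.min(abs(ct$lag_axis - 12))
  i2 <- which.min(abs(ct$lag_axis - 30))
  win <- -3:3
  expect_equal(ct$lag_axis[i1 + win][which.max(ct$envelope[i1 + win])], 12, tolerance = 0.05)
  expect_equal(ct$lag_axis[i2 + win][which.max(ct$envelope[i2 + win])], 30, tolerance = 0.05)
  expect_equal(max(ct$envelope[i2 + win]) / max(ct$envelope[i1 + win]), 0.7, tolerance = 0.03)
})

test_that("simulate-compress round trip recovers ground-truth delays for random positions", {
  lay <- sparsify_layout(fix_layout, 13)
  set.seed(7)
  for (rep in 1:6) {
    p <- c(stats::runif(1, -8, 8), stats::runif(1, -8, 8), stats::runif(1, 10, 45))
    fr <- synthesize_frame(lay, acoustic_scene(p), fix_spec, 60)
    cf <- compress_frame(fr, fix_chirp)
    got <- cf$lag_axis[apply(cf$envelope, 2, which.max)]
    expect_lt(max(abs(got - fr$true_delays)), 1 / (2 * fix_fs))
  }
})

test_that("matched filtering in white noise raises envelope SNR by about sqrt(T*B)", {
  # quick Monte-Carlo version of the compression-gain check (in-band reference)
  n <- round(40 * fix_fs)
  lag <- (0:(n - 1)) / fix_fs
  clean <- placed_trace(fix_chirp, 15, fix_fs, n)
  set.seed(5)
  gains <- replicate(60, {
    x <- clean + stats::rnorm(n, sd = 0.02)
    snr_raw <- measure_snr(signal_envelope(bandpass_filter(x, fix_fs)), lag)
    ct <- pulse_compress(x, fix_chirp, fix_fs)
    measure_snr(ct$envelope, ct$lag_axis) / snr_raw
  })
  expect_equal(mean(gains), sqrt(5 * 4), tolerance = 0.15)
})
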