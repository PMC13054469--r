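# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code at test time; no stored data.

fix_layout <- fermat_spiral_layout(256)
fix_spec <- chirp_spec()          # 1-5 MHz, 5 us, 26 MHz
fix_chirp <- make_chirp(fix_spec)
fix_fs <- fix_spec$sample_rate

# Geometric one-way delays (us): independent of the simulator internals.
geom_delays <- function(layout, p, c_mm_us = 1.48) {
  pos <- element_positions(layout)
  sqrt((p[1] - pos[, 1])^2 + (p[2] - pos[, 2])^2 + (p[3] - pos[, 3])^2) / c_mm_us
}

# Independent fractional-delay oracle: band-limited (sinc) interpolation of a
# template onto a shifted grid. Used to build fixtures with known sub-sample
# delays without touching the simulator's frequency-domain shift.
sinc_delay <- function(template, delay_us, fs, n_out) {
  t_out <- (seq_len(n_out) - 1) / fs
  x <- numeric(n_out)
  t_in <- (seq_along(template) - 1) / fs
  for (k in seq_along(template)) {
    arg <- (t_out - delay_us - t_in[k]) * fs
    x <- x + template[k] * sinc(arg)
  }
  x
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

# Noiseless single-element trace with an arrival of given amplitude/delay
# (integer-sample placement; exact by construction).
placed_trace <- function(template, delay_us, fs, n_out, amp = 1) {
  d <- round(delay_us * fs)
  stopifnot(d >= 0, d + length(template) <= n_out)
  c(numeric(d), amp * template, numeric(n_out - d - length(template)))
}

# Euclidean localization error
loc_error <- function(est, truth) sqrt(sum((est - truth)^2))

# Subset a toa_decisions frame by element id, keeping its class.
subset_decisions <- function(dec, ids) {
  out <- dec[dec$element_id %in% ids, , drop = FALSE]
  class(out) <- class(dec)
  out
}
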