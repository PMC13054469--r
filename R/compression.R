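#' Zero-phase bandpass filter
#'
#' Suppresses out-of-band noise with a Butterworth bandpass applied
#' forward-backward (`signal::filtfilt`), so the net group delay is zero and
#' filtering does not bias arrival-time estimates. A causal filter would shift
#' every peak by its group delay; the zero-phase realization is a hard
#' requirement of the timing chain, not a stylistic choice.
#'
#' @param x numeric sample vector.
#' @param sample_rate sampling rate in MHz.
#' @param f_lo,f_hi band edges in MHz (defaults 1 and 5, the excitation band).
#' @param order analog prototype order of the Butterworth design (default 4;
#'   the bandpass transformation and the forward-backward pass steepen the
#'   effective rolloff further).
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(x, sample_rate, f_lo = 1, f_hi = 5, order = 4) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < sample_rate / 2)) {
    stop_needletrack("filter_design", "need 0 < f_lo < f_hi < sample_rate/2")
  }
  bf <- signal::butter(order / 2, c(f_lo, f_hi) / (sample_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Envelope via the analytic signal
#'
#' @param x numeric sample vector.
#' @return The magnitude of the analytic signal of `x` (Hilbert envelope);
#'   for a narrowband signal this traces the peaks of `abs(x)`.
#' @export
signal_envelope <- function(x) {
  Mod(analytic_signal(x))
}

#' Matched-filter pulse compression
#'
#' Cross-correlates a received trace with the transmit template (equivalently,
#' convolves with the time-reversed template), concentrating the energy of a
#' long coded pulse into a short peak. The lag axis is calibrated to the
#' excitation start: a noiseless trace containing the template delayed by
#' tau yields an envelope peak at lag tau. The output is normalized by the
#' template energy, so the envelope peak approximates the amplitude of the
#' received copy.
#'
#' @param x numeric received trace.
#' @param template transmit waveform samples (length <= length(x)).
#' @param sample_rate sampling rate in MHz.
#' @return An object of class `compressed_trace` with fields `samples`
#'   (compressed signal), `analytic` (its analytic signal), `envelope`,
#'   `lag_axis` (us, spacing 1/sample_rate) and `sample_rate`.
#' @export
pulse_compress <- function(x, template, sample_rate) {
  if (length(x) == 0L || length(template) == 0L) {
    stop_needletrack("invalid_signal", "empty trace or template")
  }
  if (length(template) > length(x)) {
    stop_needletrack("invalid_signal", "template longer than trace")
  }
  n <- length(x)
  nfft <- next_pow2(n + length(template))
  X <- stats::fft(c(x, numeric(nfft - n)))
  C <- stats::fft(c(template, numeric(nfft - length(template))))
  cc <- Re(stats::fft(X * Conj(C), inverse = TRUE)) / nfft
  samples <- cc[seq_len(n)] / sum(template^2)
  structure(
    list(
      samples = samples,
      analytic = analytic_signal(samples),
      envelope = Mod(analytic_signal(samples)),
      lag_axis = (seq_len(n) - 1) / sample_rate,
      sample_rate = sample_rate
    ),
    class = "compressed_trace"
  )
}

#' @export
print.compressed_trace <- function(x, ...) {
  i <- which.max(x$envelope)
  cat(sprintf(
    "<compressed_trace> %d lags @ %g MHz; envelope peak %.3g at %.2f us\n",
    length(x$samples), x$sample_rate, x$envelope[i], x$lag_axis[i]
  ))
  invisible(x)
}

#' Bandpass-filter and pulse-compress every trace of a frame
#'
#' Runs the per-element receive chain (zero-phase bandpass, matched filter,
#' envelope detection) over all traces of a frame at once. This is the shared
#' front end of both the arrival-time gating chain and the delay-and-sum
#' baseline.
#'
#' @param frame an [rf_frame()].
#' @param template transmit waveform samples.
#' @param band bandpass edges in MHz, or `NULL` to skip filtering.
#' @return An object of class `compressed_frame`: matrices `samples`,
#'   `envelope` (real) and `analytic` (complex), one column per element,
#'   plus `lag_axis`, `sample_rate` and `element_ids`.
#' @export
compress_frame <- function(frame, template, band = c(1, 5)) {
  stopifnot(inherits(frame, "rf_frame"))
  fs <- frame$sample_rate
  n <- nrow(frame$traces)
  traces <- frame$traces
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
    for (j in seq_len(ncol(traces))) {
      traces[, j] <- signal::filtfilt(bf, traces[, j])
    }
  }
  nfft <- next_pow2(n + length(template))
  C <- stats::fft(c(template, numeric(nfft - length(template))))
  pad <- matrix(0, nfft - n, ncol(traces))
  X <- stats::mvfft(rbind(traces, pad))
  cc <- Re(stats::mvfft(X * Conj(C), inverse = TRUE)) / nfft
  samples <- cc[seq_len(n), , drop = FALSE] / sum(template^2)
  # analytic signal of every column in one pass
  S <- stats::mvfft(samples)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::mvfft(S * h, inverse = TRUE) / n
  structure(
    list(
      samples = samples,
      analytic = analytic,
      envelope = Mod(analytic),
      lag_axis = (seq_len(n) - 1) / fs,
      sample_rate = fs,
      element_ids = frame$element_ids
    ),
    class = "compressed_frame"
  )
}

#' @export
print.compressed_frame <- function(x, ...) {
  cat(sprintf("<compressed_frame> %d elements x %d lags @ %g MHz\n",
              ncol(x$samples), nrow(x$samples), x$sample_rate))
  invisible(x)
}

# View one element of a compressed frame as a compressed_trace.
compressed_trace_of <- function(cframe, j) {
  structure(
    list(
      samples = cframe$samples[, j],
      analytic = cframe$analytic[, j],
      envelope = cframe$envelope[, j],
      lag_axis = cframe$lag_axis,
      sample_rate = cframe$sample_rate
    ),
    class = "compressed_trace"
  )
}
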