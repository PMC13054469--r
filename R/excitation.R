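#' Describe a transmit excitation
#'
#' Two excitation modes are supported: a linear frequency-modulated chirp
#' (default: 5 us sweep from 1 to 5 MHz) and a Gaussian-windowed tone burst
#' (default: four cycles at 3 MHz centre frequency). All traces are sampled at
#' `sample_rate` MHz (default 26 MHz). Units follow the package convention:
#' MHz and microseconds, so one sample spans `1/sample_rate` us.
#'
#' @param f_start,f_stop chirp start/stop frequencies in MHz.
#' @param duration chirp duration in us.
#' @param f_center tone-burst centre frequency in MHz.
#' @param n_cycles number of carrier periods between the Gaussian window's
#'   half-amplitude points.
#' @param sample_rate sampling rate in MHz.
#' @return An object of class `excitation_spec`.
#' @export
chirp_spec <- function(f_start = 1, f_stop = 5, duration = 5, sample_rate = 26) {
  spec <- structure(
    list(kind = "chirp", f_start = f_start, f_stop = f_stop,
         duration = duration, sample_rate = sample_rate),
    class = "excitation_spec"
  )
  validate_excitation(spec)
  spec
}

#' @rdname chirp_spec
#' @export
toneburst_spec <- function(f_center = 3, n_cycles = 4, sample_rate = 26) {
  spec <- structure(
    list(kind = "toneburst", f_center = f_center, n_cycles = n_cycles,
         sample_rate = sample_rate),
    class = "excitation_spec"
  )
  validate_excitation(spec)
  spec
}

validate_excitation <- function(spec) {
  if (!spec$sample_rate > 0) {
    stop_needletrack("invalid_excitation", "sample_rate must be > 0")
  }
  if (spec$kind == "chirp") {
    ok <- spec$f_start > 0 && spec$f_stop >= spec$f_start &&
      spec$f_stop < spec$sample_rate / 2 && spec$duration > 0
    if (!ok) {
      stop_needletrack(
        "invalid_excitation",
        "chirp needs 0 < f_start <= f_stop < sample_rate/2 and duration > 0"
      )
    }
  } else if (spec$kind == "toneburst") {
    ok <- spec$f_center > 0 && spec$f_center < spec$sample_rate / 2 &&
      spec$n_cycles >= 1
    if (!ok) {
      stop_needletrack(
        "invalid_excitation",
        "tone burst needs 0 < f_center < sample_rate/2 and n_cycles >= 1"
      )
    }
  } else {
    stop_needletrack("invalid_excitation", "unknown excitation kind '%s'", spec$kind)
  }
  invisible(spec)
}

#' @export
print.excitation_spec <- function(x, ...) {
  if (x$kind == "chirp") {
    cat(sprintf("<excitation_spec> linear chirp %g-%g MHz, %g us @ %g MHz\n",
                x$f_start, x$f_stop, x$duration, x$sample_rate))
  } else {
    cat(sprintf("<excitation_spec> Gaussian tone burst, %g cycles @ %g MHz, fs %g MHz\n",
                x$n_cycles, x$f_center, x$sample_rate))
  }
  invisible(x)
}

#' Synthesize an excitation waveform
#'
#' `make_chirp()` returns a linear FM sinusoid whose instantaneous frequency
#' sweeps from `f_start` at t = 0 to `f_stop` at t = `duration`;
#' `make_toneburst()` returns a Gaussian-windowed sinusoid whose envelope
#' spans `n_cycles` carrier periods between its half-amplitude points.
#' `make_excitation()` dispatches on the spec kind. All waveforms are
#' normalized to unit peak amplitude and start at the transmit trigger (t = 0).
#'
#' @param spec an [chirp_spec()] or [toneburst_spec()].
#' @return Numeric sample vector at `spec$sample_rate` MHz.
#' @export
make_chirp <- function(spec) {
  validate_excitation(spec)
  if (spec$kind != "chirp") {
    stop_needletrack("invalid_excitation", "make_chirp needs a chirp spec")
  }
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  rate <- (spec$f_stop - spec$f_start) / spec$duration
  phase <- 2 * pi * (spec$f_start * t + 0.5 * rate * t^2)
  x <- sin(phase)
  x / max(abs(x))
}

#' @rdname make_chirp
#' @export
make_toneburst <- function(spec) {
  validate_excitation(spec)
  if (spec$kind != "toneburst") {
    stop_needletrack("invalid_excitation", "make_toneburst needs a toneburst spec")
  }
  fwhm <- spec$n_cycles / spec$f_center            # us between half-amplitude points
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half_span <- fwhm / 2 + 3 * sigma                # keep tails to ~1% of peak
  n <- 2 * round(half_span * spec$sample_rate) + 1
  t <- (seq_len(n) - (n + 1) / 2) / spec$sample_rate
  x <- exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * spec$f_center * t)
  x / max(abs(x))
}

#' @rdname make_chirp
#' @export
make_excitation <- function(spec) {
  validate_excitation(spec)
  if (spec$kind == "chirp") make_chirp(spec) else make_toneburst(spec)
}
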