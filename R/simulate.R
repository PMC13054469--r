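#' Describe an acoustic scene
#'
#' The scene places a point-like omnidirectional receiver (the fiber-optic
#' hydrophone at the needle tip) in front of the array face and fixes the
#' propagation model: constant sound speed, spherical-spreading amplitude
#' decay, optional discrete multipath echoes, optional frequency-proportional
#' attenuation, and additive white Gaussian noise.
#'
#' @param receiver_position 3-vector (mm) with z > 0 (into the medium).
#' @param sound_speed speed of sound in mm/us (default 1.48, water at ~20 C).
#' @param noise_sigma standard deviation of additive Gaussian noise, in the
#'   same linear amplitude units as the received traces (a receiver at 1 mm
#'   would record the excitation at unit amplitude).
#' @param multipath optional data frame / list with `extra_delay` (us, > 0)
#'   and `relative_amplitude` (> 0, relative to the direct arrival), one row
#'   per discrete echo replicated on every element.
#' @param attenuation optional attenuation coefficient in dB/(MHz cm); `NULL`
#'   (default) disables it, matching water-tank conditions.
#' @param rng_seed integer seed making the synthesized noise reproducible.
#' @return An object of class `acoustic_scene`.
#' @export
acoustic_scene <- function(receiver_position, sound_speed = 1.48,
                           noise_sigma = 0, multipath = NULL,
                           attenuation = NULL, rng_seed = 1L) {
  receiver_position <- as.numeric(receiver_position)
  if (length(receiver_position) != 3 || anyNA(receiver_position)) {
    stop_needletrack("invalid_scene", "receiver_position must be a numeric 3-vector")
  }
  if (receiver_position[3] <= 0) {
    stop_needletrack("invalid_scene", "receiver z must be > 0 (in front of the array)")
  }
  if (sound_speed <= 0) stop_needletrack("invalid_scene", "sound_speed must be > 0")
  if (noise_sigma < 0) stop_needletrack("invalid_scene", "noise_sigma must be >= 0")
  if (!is.null(multipath)) {
    multipath <- as.data.frame(multipath)
    if (!all(c("extra_delay", "relative_amplitude") %in% names(multipath))) {
      stop_needletrack("invalid_scene", "multipath needs extra_delay and relative_amplitude")
    }
    if (any(multipath$extra_delay <= 0) || any(multipath$relative_amplitude <= 0)) {
      stop_needletrack("invalid_scene", "multipath delays and amplitudes must be > 0")
    }
  }
  structure(
    list(receiver_position = receiver_position, sound_speed = sound_speed,
         noise_sigma = noise_sigma, multipath = multipath,
         attenuation = attenuation, rng_seed = as.integer(rng_seed)),
    class = "acoustic_scene"
  )
}

#' @export
print.acoustic_scene <- function(x, ...) {
  cat(sprintf(
    "<acoustic_scene> receiver (%.2f, %.2f, %.2f) mm, c = %g mm/us, noise sigma = %g%s\n",
    x$receiver_position[1], x$receiver_position[2], x$receiver_position[3],
    x$sound_speed, x$noise_sigma,
    if (is.null(x$multipath)) "" else sprintf(", %d multipath echo(es)", nrow(x$multipath))
  ))
  invisible(x)
}

#' Construct an RF frame
#'
#' One tracking acquisition: one received trace per sequentially excited
#' element, all on a common time axis starting at the transmit trigger
#' (t0 = 0 us).
#'
#' @param traces numeric matrix, one column per element (rows are samples).
#' @param sample_rate sampling rate in MHz.
#' @param element_ids integer ids aligned with the columns of `traces`.
#' @param t0 time of the transmit trigger in us (0 by convention).
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(traces, sample_rate, element_ids, t0 = 0) {
  traces <- as.matrix(traces)
  if (!is.numeric(traces) || nrow(traces) < 1L) {
    stop_needletrack("invalid_frame", "traces must be a non-empty numeric matrix")
  }
  if (sample_rate <= 0) stop_needletrack("invalid_frame", "sample_rate must be > 0")
  element_ids <- as.integer(element_ids)
  if (length(element_ids) != ncol(traces) || anyDuplicated(element_ids)) {
    stop_needletrack("invalid_frame", "element_ids must be distinct and match trace columns")
  }
  colnames(traces) <- as.character(element_ids)
  structure(
    list(traces = traces, sample_rate = sample_rate,
         element_ids = element_ids, t0 = t0),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d elements x %d samples @ %g MHz (%.1f us)\n",
              ncol(x$traces), nrow(x$traces), x$sample_rate,
              nrow(x$traces) / x$sample_rate))
  invisible(x)
}

#' Time axis of an RF frame
#'
#' @param frame an [rf_frame()].
#' @return Sample times in us relative to the transmit trigger.
#' @export
frame_times <- function(frame) {
  stopifnot(inherits(frame, "rf_frame"))
  frame$t0 + (seq_len(nrow(frame$traces)) - 1) / frame$sample_rate
}

#' Synthesize per-element received traces for a point receiver
#'
#' For each element i the trace contains the excitation waveform delayed by
#' the one-way propagation time \eqn{\tau_i = \|p - s_i\| / c} and scaled by
#' \eqn{1/\|p - s_i\|} (distances in mm, so a receiver at 1 mm records unit
#' amplitude), plus one scaled copy per multipath echo at
#' \eqn{\tau_i + \Delta}, plus i.i.d. Gaussian noise. Delays are applied with
#' sub-sample accuracy by a frequency-domain phase ramp on a zero-padded
#' (>= 2x) grid, so the ground-truth arrival time is exact by construction and
#' never quantized to the sample grid. The transmit trigger defines t = 0 and
#' the excitation starts at t = 0, so the arrival time is the delay of the
#' excitation's start.
#'
#' @param layout an [element_layout()] of transmitting elements.
#' @param scene an [acoustic_scene()].
#' @param spec an excitation spec ([chirp_spec()] / [toneburst_spec()]).
#' @param trace_duration trace length in us; must exceed the largest
#'   propagation delay plus the excitation duration.
#' @return An [rf_frame()] with an extra `true_delays` field (named vector,
#'   us) recording the exact per-element one-way delays for validation.
#'   Identical seeds give bit-identical frames.
#' @export
synthesize_frame <- function(layout, scene, spec, trace_duration = 60) {
  stopifnot(inherits(layout, "element_layout"), inherits(scene, "acoustic_scene"))
  template <- make_excitation(spec)
  fs <- spec$sample_rate
  pos <- element_positions(layout)
  p <- scene$receiver_position
  dist <- sqrt((p[1] - pos[, 1])^2 + (p[2] - pos[, 2])^2 + (p[3] - pos[, 3])^2)
  tau <- dist / scene$sound_speed

  n_out <- round(trace_duration * fs)
  max_extra <- if (is.null(scene$multipath)) 0 else max(scene$multipath$extra_delay)
  need <- max(tau) + max_extra + length(template) / fs
  if (trace_duration <= need) {
    stop_needletrack(
      "truncation",
      "trace_duration %.1f us too short: arrivals extend to %.1f us", trace_duration, need
    )
  }
  if (min(tau) < 5) {
    warning(sprintf(
      "first arrival at %.2f us falls inside the default 5 us noise-baseline window",
      min(tau)
    ), call. = FALSE)
  }

  nfft <- next_pow2(2 * n_out)
  f <- fft_freqs(nfft, fs)
  Xc <- stats::fft(c(template, numeric(nfft - length(template))))
  if (!is.null(scene$attenuation)) {
    # alpha dB/(MHz cm); one-way path length dist mm -> dist/10 cm.
    # Applied per element below (depends on distance); keep spectrum template.
    atten <- TRUE
  } else {
    atten <- FALSE
  }

  # delay kernels: nfft x n matrix of exp(-2i pi f tau_i), scaled by 1/dist
  arrivals <- cbind(delay = tau, amp = 1 / dist)
  if (!is.null(scene$multipath)) {
    for (m in seq_len(nrow(scene$multipath))) {
      arrivals <- rbind(arrivals, cbind(
        delay = tau + scene$multipath$extra_delay[m],
        amp = scene$multipath$relative_amplitude[m] / dist
      ))
    }
  }
  n_el <- nrow(pos)
  spec_mat <- matrix(0 + 0i, nrow = nfft, ncol = n_el)
  for (a in seq_len(nrow(arrivals) / n_el)) {
    idx <- (a - 1) * n_el + seq_len(n_el)
    ramp <- exp(-2i * pi * outer(f, arrivals[idx, "delay"]))
    spec_mat <- spec_mat + sweep(ramp, 2, arrivals[idx, "amp"], `*`) * Xc
  }
  if (atten) {
    # |H(f)| = 10^(-alpha |f| (dist/10) / 20) per element
    att_mat <- outer(abs(f), scene$attenuation * dist / 10,
                     function(fr, ad) 10^(-fr * ad / 20))
    spec_mat <- spec_mat * att_mat
  }
  traces <- Re(stats::mvfft(spec_mat, inverse = TRUE)) / nfft
  traces <- traces[seq_len(n_out), , drop = FALSE]

  if (scene$noise_sigma > 0) {
    noise <- with_seed(scene$rng_seed, matrix(
      stats::rnorm(n_out * n_el, sd = scene$noise_sigma), nrow = n_out
    ))
    traces <- traces + noise
  }
  frame <- rf_frame(traces, fs, layout$element_id)
  frame$true_delays <- stats::setNames(tau, layout$element_id)
  frame
}

#' Read or write an RF frame
#'
#' The on-disk container is plain text: a CSV with one column per element
#' (header `e<id>`) and a JSON metadata sidecar `<path>.meta.json` holding
#' `sample_rate_mhz`, `t0_us` and `element_ids`.
#'
#' @param frame an [rf_frame()].
#' @param path CSV file path.
#' @return `write_rf_frame` returns `path` invisibly; `read_rf_frame` returns
#'   an [rf_frame()].
#' @export
write_rf_frame <- function(frame, path) {
  stopifnot(inherits(frame, "rf_frame"))
  d <- as.data.frame(frame$traces)
  names(d) <- paste0("e", frame$element_ids)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(sample_rate_mhz = frame$sample_rate, t0_us = frame$t0,
               element_ids = frame$element_ids)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    ids <- meta$element_ids
    fs <- meta$sample_rate_mhz
    t0 <- meta$t0_us
  } else {
    ids <- as.integer(sub("^e", "", names(d)))
    fs <- 26
    t0 <- 0
    warning("no metadata sidecar found; assuming 26 MHz sampling and t0 = 0", call. = FALSE)
  }
  rf_frame(as.matrix(d), fs, ids, t0)
}
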