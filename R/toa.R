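#' Reliability-gate configuration for arrival-time estimation
#'
#' Two gates decide whether a per-element arrival time is trustworthy:
#'
#' * a noise gate comparing the envelope peak against the baseline noise level
#'   `sigma` (standard deviation of the compressed envelope over the first
#'   `baseline_window` us, where no arrival is expected), and
#' * a consistency gate rejecting traces whose supra-half-maximum
#'   centre of mass (CoM) is farther than `com_delay_limit` us from the peak
#'   time — the signature of strong multipath echoes.
#'
#' @param sigma_multiplier noise-gate multiplier on sigma (default 4).
#' @param com_delay_limit maximum |CoM - peak| in us (default 2).
#' @param baseline_window baseline noise window in us (default 5).
#' @param width_mode `"amplitude_gate"` (default) rejects a trace as noisy
#'   when the half-maximum level `A50 = 0.5 * peak` falls below
#'   `sigma_multiplier * sigma`, i.e. the peak is weak relative to noise.
#'   `"literal_width"` instead compares the half-maximum width, counted in
#'   samples, against `sigma_multiplier * sigma` in amplitude units; this mode
#'   mixes units and is provided for sensitivity analysis only (see the
#'   methods vignette).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(sigma_multiplier = 4, com_delay_limit = 2,
                        baseline_window = 5,
                        width_mode = c("amplitude_gate", "literal_width")) {
  width_mode <- match.arg(width_mode)
  if (sigma_multiplier <= 0 || com_delay_limit <= 0 || baseline_window <= 0) {
    stop_needletrack("invalid_gates", "all gate parameters must be positive")
  }
  structure(
    list(sigma_multiplier = sigma_multiplier, com_delay_limit = com_delay_limit,
         baseline_window = baseline_window, width_mode = width_mode),
    class = "gate_config"
  )
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf(
    "<gate_config> noise gate: %s (k = %g), |CoM - peak| <= %g us, baseline < %g us\n",
    x$width_mode, x$sigma_multiplier, x$com_delay_limit, x$baseline_window
  ))
  invisible(x)
}

#' Width of the main peak above half maximum
#'
#' Returns the width (us) of the contiguous region containing the global
#' envelope peak where the envelope stays at or above `A50 = 0.5 * max`,
#' with linear interpolation at the half-maximum crossings. Peak ties are
#' broken by the earliest lag.
#'
#' @param envelope non-negative envelope samples.
#' @param lag_axis uniformly spaced lag values in us.
#' @return Width in us.
#' @export
half_max_width <- function(envelope, lag_axis) {
  check_envelope(envelope, lag_axis)
  i <- which.max(envelope)
  a50 <- envelope[i] / 2
  n <- length(envelope)
  # walk left
  l <- i
  while (l > 1 && envelope[l - 1] >= a50) l <- l - 1
  if (l > 1) {
    # interpolate crossing between l-1 (below) and l (above)
    frac <- (a50 - envelope[l - 1]) / (envelope[l] - envelope[l - 1])
    t_left <- lag_axis[l - 1] + frac * (lag_axis[l] - lag_axis[l - 1])
  } else {
    t_left <- lag_axis[1]
  }
  r <- i
  while (r < n && envelope[r + 1] >= a50) r <- r + 1
  if (r < n) {
    frac <- (envelope[r] - a50) / (envelope[r] - envelope[r + 1])
    t_right <- lag_axis[r] + frac * (lag_axis[r + 1] - lag_axis[r])
  } else {
    t_right <- lag_axis[n]
  }
  t_right - t_left
}

#' Centre of mass of all supra-half-maximum content
#'
#' Amplitude-weighted mean lag over *all* samples whose envelope is at or
#' above half the global maximum — including secondary lobes and late echoes,
#' not just the main lobe. Including everything above threshold is what makes
#' the |CoM - peak| gate sensitive to multipath: a strong echo drags the CoM
#' away from the peak.
#'
#' @inheritParams half_max_width
#' @return CoM lag in us.
#' @export
com_above_half_max <- function(envelope, lag_axis) {
  check_envelope(envelope, lag_axis)
  a50 <- max(envelope) / 2
  sel <- envelope >= a50
  sum(lag_axis[sel] * envelope[sel]) / sum(envelope[sel])
}

check_envelope <- function(envelope, lag_axis) {
  if (length(envelope) < 3L || length(envelope) != length(lag_axis)) {
    stop_needletrack("invalid_signal", "envelope and lag_axis must match, length >= 3")
  }
  if (max(envelope) <= min(envelope)) {
    stop_needletrack("degenerate_signal", "flat envelope has no defined peak")
  }
  invisible(TRUE)
}

#' Detect reliable per-element arrival times
#'
#' Runs the receive chain (zero-phase bandpass, matched-filter compression,
#' envelope detection) on every trace of a frame and applies the reliability
#' gates in order: the noise gate first, then the peak-to-CoM consistency
#' gate. Only elements passing both gates are marked accepted; their arrival
#' time is the envelope-peak lag refined by three-point parabolic
#' interpolation (sub-sample accuracy, no phase-based refinement).
#'
#' @param frame an [rf_frame()].
#' @param template transmit waveform samples (the matched-filter template).
#' @param gates a [gate_config()].
#' @param band bandpass edges in MHz (`NULL` skips filtering).
#' @return A data frame of class `toa_decisions` with one row per element:
#'   `element_id`, `peak_toa` (us), `half_max_width` (us), `com_time` (us),
#'   `baseline_sigma`, `peak_amplitude`, `accepted`,
#'   `rejection_reason` (`"none"`, `"noisy"` or `"inconsistent"`).
#' @details An all-rejected frame is not an error here; downstream position
#'   solving decides whether enough observations remain.
#' @export
detect_reliable_toas <- function(frame, template, gates = gate_config(),
                                 band = c(1, 5)) {
  stopifnot(inherits(frame, "rf_frame"), inherits(gates, "gate_config"))
  cf <- compress_frame(frame, template, band = band)
  detect_reliable_toas_compressed(cf, gates)
}

# Gate an already-compressed frame (shared with the sweep driver, which
# compresses once and gates/solves many nested subsets).
detect_reliable_toas_compressed <- function(cf, gates = gate_config()) {
  n_el <- ncol(cf$envelope)
  lag <- cf$lag_axis
  dt <- 1 / cf$sample_rate
  base_idx <- lag < gates$baseline_window
  if (!any(base_idx)) {
    stop_needletrack("invalid_frame", "traces shorter than the baseline window")
  }
  out <- data.frame(
    element_id = cf$element_ids,
    peak_toa = NA_real_, half_max_width = NA_real_, com_time = NA_real_,
    baseline_sigma = NA_real_, peak_amplitude = NA_real_,
    accepted = FALSE, rejection_reason = "none",
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_el)) {
    env <- cf$envelope[, j]
    if (max(env) <= min(env)) {
      out$rejection_reason[j] <- "noisy"
      next
    }
    i <- which.max(env)
    peak <- env[i]
    a50 <- peak / 2
    sigma <- stats::sd(env[base_idx])
    hw <- half_max_width(env, lag)
    com <- com_above_half_max(env, lag)
    out$peak_toa[j] <- refine_peak(env, lag, i, dt)
    out$half_max_width[j] <- hw
    out$com_time[j] <- com
    out$baseline_sigma[j] <- sigma
    out$peak_amplitude[j] <- peak
    noisy <- if (gates$width_mode == "amplitude_gate") {
      a50 < gates$sigma_multiplier * sigma
    } else {
      (hw / dt) < gates$sigma_multiplier * sigma
    }
    if (noisy) {
      out$rejection_reason[j] <- "noisy"
    } else if (abs(com - lag[i]) > gates$com_delay_limit) {
      out$rejection_reason[j] <- "inconsistent"
    } else {
      out$accepted[j] <- TRUE
    }
  }
  class(out) <- c("toa_decisions", "data.frame")
  out
}

# Three-point parabolic refinement of the envelope-peak lag.
refine_peak <- function(env, lag, i, dt) {
  n <- length(env)
  if (i <= 1L || i >= n) return(lag[i])
  denom <- env[i - 1] - 2 * env[i] + env[i + 1]
  if (denom >= 0) return(lag[i])   # not a strict local maximum of the parabola
  delta <- 0.5 * (env[i - 1] - env[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  lag[i] + delta * dt
}

#' @export
print.toa_decisions <- function(x, ...) {
  cat(sprintf("<toa_decisions> %d elements: %d accepted, %d noisy, %d inconsistent\n",
              nrow(x), sum(x$accepted),
              sum(x$rejection_reason == "noisy"),
              sum(x$rejection_reason == "inconsistent")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Export arrival-time decisions as CSV
#'
#' Columns: `element_id,peak_toa_us,half_max_width_us,com_time_us,sigma,`
#' `peak_amplitude,accepted,reason`.
#'
#' @param decisions a `toa_decisions` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_toa_decisions <- function(decisions, path) {
  stopifnot(inherits(decisions, "toa_decisions"))
  d <- data.frame(
    element_id = decisions$element_id,
    peak_toa_us = decisions$peak_toa,
    half_max_width_us = decisions$half_max_width,
    com_time_us = decisions$com_time,
    sigma = decisions$baseline_sigma,
    peak_amplitude = decisions$peak_amplitude,
    accepted = decisions$accepted,
    reason = decisions$rejection_reason
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
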