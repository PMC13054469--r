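#' Define a regular tracking volume grid
#'
#' @param x,y,z voxel-centre coordinates in mm (regular, ascending). The
#'   defaults (0.2 mm isotropic voxels over x, y in \[-12, 12\] mm and z in
#'   \[5, 50\] mm) cover the tracking field of view at a resolution well below
#'   the accuracy scales of interest.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(x = seq(-12, 12, by = 0.2),
                        y = seq(-12, 12, by = 0.2),
                        z = seq(5, 50, by = 0.2)) {
  for (ax in list(x, y, z)) {
    if (length(ax) < 1L || (length(ax) > 1L && any(diff(ax) <= 0))) {
      stop_needletrack("invalid_grid", "grid axes must be ascending")
    }
  }
  structure(list(x = x, y = y, z = z), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, x [%g, %g] y [%g, %g] z [%g, %g] mm\n",
              length(x$x), length(x$y), length(x$z),
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  invisible(x)
}

#' One-way delay-and-sum tracking volume
#'
#' Reconstructs a volumetric intensity map from per-element compressed traces
#' by coherently summing, for each voxel v, the analytic compressed signal of
#' every element interpolated at the one-way delay
#' \eqn{\tau_i(v) = \|v - s_i\|/c}, then taking the magnitude of the sum
#' (envelope after summation). This is the baseline localizer: the receiver is
#' a single point hydrophone, so only transmit-side delays exist and no
#' receive beamforming applies. Linear interpolation is used between samples;
#' voxels whose delay falls outside the trace support contribute zero and
#' trigger a coverage warning.
#'
#' @param frame an [rf_frame()] (compressed internally with `template`) or a
#'   ready-made `compressed_frame` from [compress_frame()].
#' @param layout the [element_layout()]; must cover the frame's element ids.
#'   Beamforming uses exactly the elements in `layout`, so passing a
#'   sparsified layout reconstructs from that subset of traces.
#' @param grid a [volume_grid()].
#' @param sound_speed mm/us.
#' @param template transmit waveform (needed when `frame` is raw).
#' @param mode `"coherent"` (default: complex sum then envelope) or
#'   `"envelope"` (sum of per-element envelopes, for sensitivity checks).
#' @param band bandpass edges for raw frames.
#' @return An object of class `tracking_volume`: 3D `intensity` array
#'   (x, y, z), axes, `voxel_size` and the grid.
#' @export
das_beamform <- function(frame, layout, grid = volume_grid(),
                         sound_speed = 1.48, template = NULL,
                         mode = c("coherent", "envelope"), band = c(1, 5)) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "element_layout"), inherits(grid, "volume_grid"))
  if (inherits(frame, "rf_frame")) {
    if (is.null(template)) {
      stop_needletrack("invalid_signal", "a template is required to compress a raw frame")
    }
    frame <- compress_frame(frame, template, band = band)
  }
  stopifnot(inherits(frame, "compressed_frame"))
  cols <- match(layout$element_id, frame$element_ids)
  if (anyNA(cols)) {
    stop_needletrack("invalid_frame", "layout contains elements missing from the frame")
  }
  res <- .das_accumulate_cpp(
    Re(frame$analytic[, cols, drop = FALSE]),
    Im(frame$analytic[, cols, drop = FALSE]),
    element_positions(layout),
    grid$x, grid$y, grid$z,
    sound_speed, frame$sample_rate, frame$lag_axis[1],
    mode == "coherent"
  )
  if (res$misses > 0) {
    warning(sprintf(
      "%.0f voxel-element delays fell outside the trace support (zero contribution)",
      res$misses
    ), call. = FALSE)
  }
  intensity <- array(res$intensity, dim = c(length(grid$x), length(grid$y), length(grid$z)))
  structure(
    list(intensity = intensity, x = grid$x, y = grid$y, z = grid$z,
         voxel_size = c(
           if (length(grid$x) > 1) grid$x[2] - grid$x[1] else NA_real_,
           if (length(grid$y) > 1) grid$y[2] - grid$y[1] else NA_real_,
           if (length(grid$z) > 1) grid$z[2] - grid$z[1] else NA_real_
         ),
         n_elements = nrow(layout), mode = mode),
    class = "tracking_volume"
  )
}

#' @export
print.tracking_volume <- function(x, ...) {
  i <- arrayInd(which.max(x$intensity), dim(x$intensity))
  cat(sprintf(
    "<tracking_volume> %d x %d x %d voxels (%d elements); peak at (%.1f, %.1f, %.1f) mm\n",
    dim(x$intensity)[1], dim(x$intensity)[2], dim(x$intensity)[3], x$n_elements,
    x$x[i[1]], x$y[i[2]], x$z[i[3]]
  ))
  invisible(x)
}

#' Centre-of-mass localization in a tracking volume
#'
#' Intensity-weighted centroid over all voxels whose intensity is within
#' `threshold_db` of the volume maximum (amplitude convention:
#' `max * 10^(threshold_db/20)`, default -6 dB).
#'
#' @param volume a `tracking_volume` from [das_beamform()].
#' @param threshold_db negative threshold in dB relative to the peak.
#' @return 3-vector position estimate in mm.
#' @export
com_localize <- function(volume, threshold_db = -6) {
  stopifnot(inherits(volume, "tracking_volume"))
  m <- max(volume$intensity)
  if (!(m > 0)) stop_needletrack("degenerate_signal", "all-zero volume has no centroid")
  thr <- m * 10^(threshold_db / 20)
  sel <- which(volume$intensity >= thr, arr.ind = TRUE)
  w <- volume$intensity[sel]
  c(
    sum(volume$x[sel[, 1]] * w),
    sum(volume$y[sel[, 2]] * w),
    sum(volume$z[sel[, 3]] * w)
  ) / sum(w)
}
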