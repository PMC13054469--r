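#' Convert accepted arrival times to ranges
#'
#' With a constant sound speed c and an arrival time t_i measured from the
#' transmit trigger of element i, the element-to-receiver distance is
#' `d_i = c * t_i`. Only elements whose arrival passed both reliability gates
#' contribute; rejected elements are excluded from localization.
#'
#' @param decisions a `toa_decisions` data frame from [detect_reliable_toas()].
#' @param layout the [element_layout()] the frame was acquired with.
#' @param sound_speed sound speed in mm/us (default 1.48).
#' @return An object of class `range_set`: `element_ids`, `ranges` (mm),
#'   `positions` (n x 3 matrix, mm) and `sound_speed`.
#' @details Fewer than 3 accepted arrivals make the frame untrackable and
#'   raise an insufficient-observations error (three absolute ranges are the
#'   minimum that determines a 3D position).
#' @export
ranges_from_toas <- function(decisions, layout, sound_speed = 1.48) {
  stopifnot(inherits(decisions, "toa_decisions"), inherits(layout, "element_layout"))
  acc <- decisions[decisions$accepted, , drop = FALSE]
  if (nrow(acc) < 3L) {
    stop_needletrack(
      "insufficient_observations",
      "only %d accepted arrival(s); at least 3 are required", nrow(acc)
    )
  }
  idx <- match(acc$element_id, layout$element_id)
  if (anyNA(idx)) {
    stop_needletrack("invalid_frame", "decisions reference elements absent from layout")
  }
  range_set(acc$element_id, sound_speed * acc$peak_toa,
            element_positions(layout)[idx, , drop = FALSE], sound_speed)
}

#' @rdname ranges_from_toas
#' @param element_ids integer ids of the contributing elements.
#' @param ranges measured distances in mm (> 0).
#' @param positions n x 3 matrix of transmitter coordinates in mm.
#' @export
range_set <- function(element_ids, ranges, positions, sound_speed = 1.48) {
  positions <- as.matrix(positions)
  n <- length(element_ids)
  if (n < 3L) {
    stop_needletrack("insufficient_observations", "a range_set needs >= 3 entries")
  }
  if (length(ranges) != n || nrow(positions) != n || ncol(positions) != 3) {
    stop_needletrack("invalid_ranges", "element_ids, ranges and positions must align")
  }
  if (any(ranges < 0)) stop_needletrack("invalid_ranges", "ranges must be >= 0")
  structure(
    list(element_ids = as.integer(element_ids), ranges = as.numeric(ranges),
         positions = unname(positions), sound_speed = sound_speed),
    class = "range_set"
  )
}

#' @export
print.range_set <- function(x, ...) {
  cat(sprintf("<range_set> %d ranges, %.1f-%.1f mm, c = %g mm/us\n",
              length(x$ranges), min(x$ranges), max(x$ranges), x$sound_speed))
  invisible(x)
}

#' Solve the receiver position by Gauss-Newton multilateration
#'
#' Minimizes the sum of squared range residuals
#' \eqn{\sum_i (\|p - s_i\| - d_i)^2} over the receiver position p. Each
#' Gauss-Newton step linearizes the residuals with Jacobian rows
#' \eqn{(p - s_i)^T / \|p - s_i\|}; steps that would increase the objective
#' are halved (up to 8 times), so the objective never increases between
#' accepted iterates. Iteration stops when the step norm drops below `tol` or
#' after `max_iter` iterations.
#'
#' When no initial guess is given, a closed-form linearized solution is used:
#' differencing the squared sphere equations against a reference element gives
#' a linear system in the lateral coordinates (all transmitters lie in the
#' z = 0 plane), and depth follows from the sphere equations, taken positive —
#' the receiver is always in front of the probe face, which also discards the
#' mirror solution a 3-element solve would otherwise admit.
#'
#' @param ranges a [range_set()].
#' @param init optional 3-vector initial guess (mm).
#' @param tol step-norm convergence tolerance in mm (default 1e-6).
#' @param max_iter maximum Gauss-Newton iterations (default 50).
#' @return An object of class `position_estimate`: `position` (mm),
#'   `residual_rms` (mm), `n_used`, `iterations`, `converged`.
#' @export
solve_position <- function(ranges, init = NULL, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(ranges, "range_set"))
  s <- ranges$positions
  d <- ranges$ranges
  p <- if (is.null(init)) linear_init(s, d) else as.numeric(init)
  if (length(p) != 3) stop_needletrack("invalid_ranges", "init must be a 3-vector")

  obj <- function(p) {
    dist <- sqrt(rowSums(sweep(s, 2, p, `-`)^2))
    sum((dist - d)^2)
  }
  f0 <- obj(p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    diff <- sweep(-s, 2, p, `+`)          # p - s_i per row
    dist <- sqrt(rowSums(diff^2))
    r <- dist - d
    # at a transmitter the residual gradient is undefined; its Jacobian row
    # is zeroed and the remaining rows carry the step
    J <- diff / pmax(dist, 1e-12)
    J[dist < 1e-12, ] <- 0
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      stop_needletrack("geometry_degenerate", "rank-deficient Jacobian (collinear elements?)")
    }
    # damping: halve the step while it increases the objective
    lambda <- 1
    for (h in 0:8) {
      p_new <- p + lambda * step
      f_new <- obj(p_new)
      if (f_new <= f0 + 1e-15) break
      lambda <- lambda / 2
    }
    if (f_new > f0 + 1e-15) {
      break                              # no acceptable step; stop with diagnostics
    }
    p <- p_new
    f0 <- f_new
    if (vec_norm(lambda * step) < tol) {
      converged <- TRUE
      break
    }
  }
  res <- residual_report(ranges, p)
  structure(
    list(position = p, residual_rms = sqrt(mean(res^2)),
         n_used = length(d), iterations = iter, converged = converged),
    class = "position_estimate"
  )
}

# Closed-form linearized initializer: subtracting the squared sphere equation
# of a reference element cancels the quadratic term and (with all elements at
# z = 0) leaves a linear system in (x, y); z then follows from the spheres.
linear_init <- function(s, d) {
  i0 <- 1L
  A <- 2 * sweep(s[-i0, 1:2, drop = FALSE], 2, s[i0, 1:2], `-`)
  b <- (d[i0]^2 - d[-i0]^2) + rowSums(s[-i0, 1:2, drop = FALSE]^2) - sum(s[i0, 1:2]^2)
  qrA <- qr(A)
  if (qrA$rank < 2) {
    stop_needletrack("geometry_degenerate", "transmitters are collinear; position not identifiable")
  }
  xy <- qr.coef(qrA, b)
  z2 <- mean(d^2 - (xy[1] - s[, 1])^2 - (xy[2] - s[, 2])^2)
  z <- sqrt(max(z2, 1e-12))
  c(xy[1], xy[2], z)
}

#' Per-element range residuals
#'
#' The residual of element i at position p is
#' \eqn{r_i = \|p - s_i\| - d_i}; the `residual_rms` of a
#' [solve_position()] estimate is the root mean square of this report at the
#' solved position.
#'
#' @param ranges a [range_set()].
#' @param position 3-vector position in mm.
#' @return Named numeric vector of residuals (mm), one per element.
#' @export
residual_report <- function(ranges, position) {
  stopifnot(inherits(ranges, "range_set"))
  position <- as.numeric(position)
  dist <- sqrt(rowSums(sweep(ranges$positions, 2, position, `-`)^2))
  stats::setNames(dist - ranges$ranges, ranges$element_ids)
}

#' @export
print.position_estimate <- function(x, ...) {
  cat(sprintf(
    "<position_estimate> (%.3f, %.3f, %.3f) mm; residual RMS %.4g mm; %d elements; %d iter%s\n",
    x$position[1], x$position[2], x$position[3], x$residual_rms, x$n_used,
    x$iterations, if (x$converged) " (converged)" else " (NOT converged)"
  ))
  invisible(x)
}

#' Exhaustive grid-search position solver
#'
#' Brute-force minimizer of the multilateration objective over a regular cube
#' of candidate positions. Orders of magnitude slower than [solve_position()];
#' intended as an independent reference for validating the Gauss-Newton
#' solver, not for production use.
#'
#' @param ranges a [range_set()].
#' @param center 3-vector cube centre (mm).
#' @param half_width half-extent of the cube in mm (default 5).
#' @param step grid spacing in mm (default 0.05).
#' @return List with `position` (best grid node) and `objective` (sum of
#'   squared residuals there).
#' @export
grid_search_position <- function(ranges, center, half_width = 5, step = 0.05) {
  stopifnot(inherits(ranges, "range_set"))
  center <- as.numeric(center)
  ax <- seq(center[1] - half_width, center[1] + half_width, by = step)
  ay <- seq(center[2] - half_width, center[2] + half_width, by = step)
  az <- seq(center[3] - half_width, center[3] + half_width, by = step)
  res <- .grid_search_cpp(ranges$positions, ranges$ranges, ax, ay, az)
  list(position = res$position, objective = res$objective)
}
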