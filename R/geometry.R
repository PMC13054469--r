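#' Construct an element layout
#'
#' An `element_layout` describes the active transducer elements of a sparse 2D
#' matrix-array probe: integer element identifiers, 3D coordinates in the probe
#' frame (millimetres; the array face is the plane z = 0, with +z pointing into
#' the medium), and a radial rank used for inner-to-outer sparsification.
#'
#' @param element_id integer vector of distinct element identifiers.
#' @param x_mm,y_mm numeric element coordinates in mm (z is 0 for all elements).
#' @return An object of class `element_layout`: a data frame with columns
#'   `element_id`, `x_mm`, `y_mm`, `z_mm` and `radial_rank`, where
#'   `radial_rank` is the 0-based rank of each element by distance from the
#'   layout centroid (0 = innermost).
#' @details Positions must be pairwise distinct. The radial rank is recomputed
#'   from the supplied coordinates, so layouts loaded from file sparsify the
#'   same way as generated ones.
#' @seealso [fermat_spiral_layout()], [sparsify_layout()], [build_plan()]
#' @export
element_layout <- function(element_id, x_mm, y_mm) {
  element_id <- as.integer(element_id)
  x_mm <- as.numeric(x_mm)
  y_mm <- as.numeric(y_mm)
  n <- length(element_id)
  if (n < 3L) {
    stop_needletrack("invalid_geometry", "an element layout needs at least 3 elements")
  }
  if (length(x_mm) != n || length(y_mm) != n) {
    stop_needletrack("invalid_geometry", "element_id, x_mm and y_mm must have equal length")
  }
  if (anyDuplicated(element_id)) {
    stop_needletrack("invalid_geometry", "element_id values must be distinct")
  }
  if (anyDuplicated(cbind(x_mm, y_mm))) {
    stop_needletrack("invalid_geometry", "element positions must be pairwise distinct")
  }
  cx <- mean(x_mm)
  cy <- mean(y_mm)
  r <- sqrt((x_mm - cx)^2 + (y_mm - cy)^2)
  # stable 0-based rank, ties broken by element_id for determinism
  ord <- order(r, element_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n) - 1L
  out <- data.frame(
    element_id = element_id,
    x_mm = x_mm,
    y_mm = y_mm,
    z_mm = 0,
    radial_rank = rank
  )
  class(out) <- c("element_layout", "data.frame")
  out
}

#' Generate a Fermat's-spiral element layout
#'
#' Places `n_elements` elements on a Fermat (parabolic) spiral,
#' \eqn{r_k = s\sqrt{k}}, \eqn{\theta_k = k\,\phi} with \eqn{\phi} the golden
#' angle, which yields a low-redundancy, approximately uniform-density sparse
#' aperture. Optionally snaps each element to the nearest free node of a
#' rectangular grid of the given pitch, emulating a physical matrix array whose
#' elements sit on a regular lattice.
#'
#' @param n_elements number of elements (>= 3).
#' @param scale_mm spiral scale \eqn{s} in mm; the outermost radius is
#'   `scale_mm * sqrt(n_elements - 1)`. The default 0.3 mm gives a 256-element
#'   aperture of about 4.8 mm radius, i.e. half of a 32 x 35 element footprint
#'   at 0.3 mm pitch.
#' @param pitch_mm grid pitch in mm for snapping, or `NULL` to keep the exact
#'   spiral coordinates. Default 0.3 mm, a plausible matrix-array pitch.
#' @return An [element_layout()] with `element_id` 1..n in spiral order
#'   (1 = centre).
#' @details Snapping collisions (two elements mapping to the same node) are
#'   resolved by moving the later element to the nearest free node within one
#'   grid diagonal of its ideal position; if no such node is free the geometry
#'   is reported infeasible. Snapping therefore never moves an element by more
#'   than `sqrt(2) * pitch_mm`.
#' @export
fermat_spiral_layout <- function(n_elements, scale_mm = 0.3, pitch_mm = 0.3) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 3L) {
    stop_needletrack("invalid_geometry", "n_elements must be an integer >= 3")
  }
  if (!is.numeric(scale_mm) || scale_mm <= 0) {
    stop_needletrack("invalid_geometry", "scale_mm must be > 0")
  }
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_elements) - 1
  r <- scale_mm * sqrt(k)
  th <- k * golden
  x <- r * cos(th)
  y <- r * sin(th)
  if (!is.null(pitch_mm)) {
    if (!is.numeric(pitch_mm) || pitch_mm <= 0) {
      stop_needletrack("invalid_geometry", "pitch_mm must be > 0 or NULL")
    }
    snapped <- snap_to_grid(x, y, pitch_mm)
    x <- snapped$x
    y <- snapped$y
  }
  element_layout(seq_len(n_elements), x, y)
}

# Snap points to grid nodes, resolving collisions to the nearest free node
# within one grid diagonal of the ideal (continuous) position.
snap_to_grid <- function(x, y, pitch) {
  n <- length(x)
  taken <- new.env(hash = TRUE, parent = emptyenv())
  ox <- numeric(n)
  oy <- numeric(n)
  # candidate node offsets within the 3x3 neighbourhood of the nearest node
  off <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in seq_len(n)) {
    ix <- round(x[i] / pitch)
    iy <- round(y[i] / pitch)
    cand_x <- (ix + off$dx) * pitch
    cand_y <- (iy + off$dy) * pitch
    d <- sqrt((cand_x - x[i])^2 + (cand_y - y[i])^2)
    ord <- order(d)
    placed <- FALSE
    for (j in ord) {
      if (d[j] > sqrt(2) * pitch + 1e-12) break
      key <- paste(ix + off$dx[j], iy + off$dy[j])
      if (!exists(key, envir = taken, inherits = FALSE)) {
        assign(key, TRUE, envir = taken)
        ox[i] <- cand_x[j]
        oy[i] <- cand_y[j]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_needletrack(
        "geometry_infeasible",
        sprintf("cannot place element %d on a %g mm grid without collision", i, pitch)
      )
    }
  }
  list(x = ox, y = oy)
}

#' Retain the k outermost elements of a layout
#'
#' Sparsification proceeds from the inner elements outwards: the size-k subset
#' keeps the k elements of largest radial rank (farthest from the layout
#' centroid). Subsets are therefore nested for decreasing k. A minimum of three
#' elements is kept, the smallest set that determines a 3D position from
#' absolute ranges.
#'
#' @param layout an [element_layout()].
#' @param k subset size, `3 <= k <= nrow(layout)`.
#' @return An `element_layout` with the k outermost elements, in `element_id`
#'   order, with radial ranks recomputed within the subset.
#' @export
sparsify_layout <- function(layout, k) {
  stopifnot(inherits(layout, "element_layout"))
  k <- as.integer(k)
  n <- nrow(layout)
  if (is.na(k) || k < 3L || k > n) {
    stop_needletrack("invalid_subset", sprintf("k must be in [3, %d], got %s", n, k))
  }
  keep <- layout$radial_rank >= (n - k)
  sub <- layout[keep, , drop = FALSE]
  sub <- sub[order(sub$element_id), , drop = FALSE]
  out <- element_layout(sub$element_id, sub$x_mm, sub$y_mm)
  rownames(out) <- NULL
  out
}

#' Build a nested sparsification plan
#'
#' @param layout an [element_layout()].
#' @param sizes strictly descending integer subset sizes, each in
#'   `[3, nrow(layout)]`.
#' @return An object of class `sparsification_plan`: a list with
#'   `subset_sizes` and `subsets` (a named list of retained `element_id`
#'   vectors, one per size). Subsets are nested: each smaller subset is
#'   contained in every larger one.
#' @export
build_plan <- function(layout, sizes) {
  stopifnot(inherits(layout, "element_layout"))
  sizes <- as.integer(sizes)
  n <- nrow(layout)
  if (length(sizes) < 1L || anyNA(sizes)) {
    stop_needletrack("invalid_plan", "sizes must be a non-empty integer vector")
  }
  if (any(diff(sizes) >= 0)) {
    stop_needletrack("invalid_plan", "sizes must be strictly descending")
  }
  if (any(sizes < 3L) || any(sizes > n)) {
    stop_needletrack("invalid_plan", sprintf("sizes must lie in [3, %d]", n))
  }
  subsets <- lapply(sizes, function(k) sparsify_layout(layout, k)$element_id)
  names(subsets) <- as.character(sizes)
  structure(
    list(subset_sizes = sizes, subsets = subsets, layout = layout),
    class = "sparsification_plan"
  )
}

#' @export
print.element_layout <- function(x, ...) {
  r <- sqrt((x$x_mm - mean(x$x_mm))^2 + (x$y_mm - mean(x$y_mm))^2)
  cat(sprintf(
    "<element_layout> %d elements, aperture radius %.2f mm (z = 0 plane)\n",
    nrow(x), max(r)
  ))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more elements\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
print.sparsification_plan <- function(x, ...) {
  cat(sprintf(
    "<sparsification_plan> sizes: %s (nested, outermost retained)\n",
    paste(x$subset_sizes, collapse = " > ")
  ))
  invisible(x)
}

#' Element positions as a matrix
#'
#' @param layout an [element_layout()].
#' @return An `n x 3` numeric matrix of positions in mm (columns x, y, z).
#' @export
element_positions <- function(layout) {
  stopifnot(inherits(layout, "element_layout"))
  m <- cbind(layout$x_mm, layout$y_mm, layout$z_mm)
  dimnames(m) <- list(layout$element_id, c("x_mm", "y_mm", "z_mm"))
  m
}

#' Read or write an element layout
#'
#' The on-disk formats are a CSV with header `element_id,x_mm,y_mm` or a JSON
#' object with the same keys (z is implied 0), so measured probe maps can be
#' substituted for the generated spiral without code changes.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_element_layout` returns an [element_layout()];
#'   `write_element_layout` returns `path` invisibly.
#' @export
read_element_layout <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
  } else {
    d <- utils::read.csv(path)
  }
  if (!all(c("element_id", "x_mm", "y_mm") %in% names(d))) {
    stop_needletrack("invalid_geometry", "geometry file needs element_id, x_mm, y_mm")
  }
  element_layout(d$element_id, d$x_mm, d$y_mm)
}

#' @rdname read_element_layout
#' @param layout an [element_layout()] to write.
#' @export
write_element_layout <- function(layout, path) {
  stopifnot(inherits(layout, "element_layout"))
  d <- data.frame(
    element_id = layout$element_id,
    x_mm = layout$x_mm,
    y_mm = layout$y_mm
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, digits = NA)
  } else {
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
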