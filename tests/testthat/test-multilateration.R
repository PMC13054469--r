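test_that("arrival times convert to ranges only for accepted elements", {
  lay <- sparsify_layout(fix_layout, 13)
  fr <- synthesize_frame(lay, acoustic_scene(c(0, 0, 20)), fix_spec, 40)
  dec <- detect_reliable_toas(fr, fix_chirp)
  rs <- ranges_from_toas(dec, lay)
  expect_length(rs$ranges, 13L)
  # d = c * t arithmetic
  dec$peak_toa[1] <- 13.5135
  rs2 <- ranges_from_toas(dec, lay)
  expect_equal(rs2$ranges[1], 20.0, tolerance = 1e-3)
  # rejected elements are excluded
  dec$accepted[1:5] <- FALSE
  expect_length(ranges_from_toas(dec, lay)$ranges, 8L)
  # fewer than three accepted -> untrackable frame
  dec$accepted[1:11] <- FALSE
  expect_error(ranges_from_toas(dec, lay),
               class = "needletrack_insufficient_observations")
})

test_that("noiseless geometric ranges are recovered to machine precision", {
  lay <- sparsify_layout(fix_layout, 13)
  p <- c(2, 4, 30)
  d <- geom_delays(lay, p) * 1.48
  rs <- range_set(lay$element_id, d, element_positions(lay))
  est <- solve_position(rs)
  expect_true(est$converged)
  expect_lt(loc_error(est$position, p), 1e-6)
  expect_lt(est$residual_rms, 1e-8)
})

test_that("a zero range anchors the solution at that transmitter", {
  lay <- sparsify_layout(fix_layout, 4)
  pos <- element_positions(lay)
  p <- pos[2, ]
  d <- unname(sqrt(rowSums(sweep(pos, 2, p, `-`)^2)))
  expect_equal(d[2], 0)
  est <- solve_position(range_set(lay$element_id, d, pos))
  expect_lt(loc_error(est$position, p), 1e-4)
})

test_that("three-element solves return the z > 0 mirror solution", {
  lay <- sparsify_layout(fix_layout, 3)
  p <- c(1, 1, 15)
  d <- geom_delays(lay, p) * 1.48
  est <- solve_position(range_set(lay$element_id, d, element_positions(lay)))
  expect_gt(est$position[3], 0)
  expect_lt(loc_error(est$position, p), 1e-5)
})

test_that("residual reports match their definition and the estimate's RMS", {
  lay <- sparsify_layout(fix_layout, 9)
  p <- c(-3, 2, 25)
  pos <- element_positions(lay)
  d <- sqrt(rowSums(sweep(pos, 2, p, `-`)^2))
  rs <- range_set(lay$element_id, d, pos)
  expect_equal(max(abs(residual_report(rs, p))), 0, tolerance = 1e-12)
  d2 <- d
  d2[4] <- d2[4] + 1
  rs2 <- range_set(lay$element_id, d2, pos)
  r <- residual_report(rs2, p)
  expect_equal(unname(r[4]), -1)
  expect_equal(sum(abs(r[-4])), 0, tolerance = 1e-12)
  set.seed(2)
  d3 <- d + stats::rnorm(9, sd = 0.1)
  rs3 <- range_set(lay$element_id, d3, pos)
  est <- solve_position(rs3)
  expect_equal(est$residual_rms, sqrt(mean(residual_report(rs3, est$position)^2)),
               tolerance = 1e-12)
})

test_that("damped Gauss-Newton never increases the objective and beats its initializer", {
  lay <- sparsify_layout(fix_layout, 13)
  pos <- element_positions(lay)
  obj <- function(q, d) sum((sqrt(rowSums(sweep(pos, 2, q, `-`)^2)) - d)^2)
  set.seed(11)
  for (i in 1:10) {
    p <- c(stats::runif(1, -6, 6), stats::runif(1, -6, 6), stats::runif(1, 10, 40))
    d <- sqrt(rowSums(sweep(pos, 2, p, `-`)^2)) + stats::rnorm(13, sd = 0.15)
    init <- p + c(2, -2, 3)
    est <- solve_position(range_set(lay$element_id, pmax(d, 0.1), pos), init = init)
    expect_lte(obj(est$position, pmax(d, 0.1)), obj(init, pmax(d, 0.1)) + 1e-12)
  }
})

test_that("the solution is invariant to element ordering", {
  lay <- sparsify_layout(fix_layout, 13)
  pos <- element_positions(lay)
  p <- c(3, -1, 28)
  set.seed(4)
  d <- sqrt(rowSums(sweep(pos, 2, p, `-`)^2)) + stats::rnorm(13, sd = 0.05)
  perm <- sample(13)
  e1 <- solve_position(range_set(lay$element_id, d, pos))
  e2 <- solve_position(range_set(lay$element_id[perm], d[perm], pos[perm, ]))
  expect_equal(e1$position, e2$position, tolerance = 1e-8)
})

test_that("collinear transmitters are reported as degenerate geometry", {
  pos <- cbind(seq(-3, 3, length.out = 5), 0, 0)
  d <- sqrt(rowSums(sweep(pos, 2, c(0, 0, 20), `-`)^2))
  expect_error(solve_position(range_set(1:5, d, pos)),
               class = "needletrack_geometry_degenerate")
})

test_that("more elements reduce error under identical ToA jitter (paired seeds)", {
  lay13 <- sparsify_layout(fix_layout, 13)
  lay4 <- sparsify_layout(fix_layout, 4)
  pos13 <- element_positions(lay13)
  idx4 <- match(lay4$element_id, lay13$element_id)
  p <- c(2, 2, 30)
  d0 <- sqrt(rowSums(sweep(pos13, 2, p, `-`)^2))
  err <- matrix(NA_real_, 120, 2)
  for (i in 1:120) {
    jit <- withr::with_seed(i, stats::rnorm(13, sd = 0.05 * 1.48))  # sigma_t = 0.05 us
    d <- d0 + jit
    e13 <- solve_position(range_set(lay13$element_id, d, pos13))
    e4 <- solve_position(range_set(lay4$element_id, d[idx4], pos13[idx4, ]))
    err[i, ] <- c(loc_error(e13$position, p), loc_error(e4$position, p))
  }
  expect_lt(mean(err[, 1]), mean(err[, 2]))
})

test_that("Gauss-Newton matches the exhaustive grid-search oracle on jittered ranges", {
  lay <- sparsify_layout(fix_layout, 13)
  pos <- element_positions(lay)
  p <- c(1, 3, 22)
  d0 <- sqrt(rowSums(sweep(pos, 2, p, `-`)^2))
  err_gn <- err_gs <- numeric(8)
  for (i in 1:8) {
    d <- d0 + withr::with_seed(100 + i, stats::rnorm(13, sd = 0.05 * 1.48))
    rs <- range_set(lay$element_id, d, pos)
    gn <- solve_position(rs)
    gs <- grid_search_position(rs, p, half_width = 3, step = 0.05)
    # along shallow (lateral) valley directions the best grid node can sit a
    # couple of steps from the continuum minimum; the solver must still be at
    # least as good as every grid node
    expect_true(all(abs(gn$position - gs$position) <= 2 * 0.05 + 1e-9))
    obj <- function(q) sum((sqrt(rowSums(sweep(pos, 2, q, `-`)^2)) - d)^2)
    expect_lte(obj(gn$position), gs$objective + 1e-9)
    err_gn[i] <- loc_error(gn$position, p)
    err_gs[i] <- loc_error(gs$position, p)
  }
  expect_equal(sqrt(mean(err_gn^2)), sqrt(mean(err_gs^2)), tolerance = 0.2)
})
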