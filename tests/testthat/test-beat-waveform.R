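test_that("centerline reconstruction matches trivial and quadrature cases", {
  s <- seq(0, 1, length.out = 2001)
  straight <- beat_pattern(s, 0, matrix(0, length(s), 1))
  tip <- reconstruct_centerline(straight, 0)[length(s), ]
  expect_equal(unname(tip), c(1, 0), tolerance = 1e-10)

  vertical <- beat_pattern(s, 0, matrix(pi / 2, length(s), 1))
  tip <- reconstruct_centerline(vertical, 0)[length(s), ]
  expect_equal(unname(tip), c(0, 1), tolerance = 1e-10)

  # psi(s) = pi/2 - 0.8 s against an independent 1e5-node quadrature oracle
  f <- function(ss) pi / 2 - 0.8 * ss
  bent <- beat_pattern(s, 0, matrix(f(s), ncol = 1))
  tip <- reconstruct_centerline(bent, 0)[length(s), ]
  expect_equal(unname(tip), unname(tip_oracle(f)), tolerance = 1e-5)
})

test_that("reconstructed centerline has unit contour length for any waveform", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(1, 0.2, 2); b <- runif(1, -0.4, 0.4)
    bp <- make_beat_pattern(a, b, n_s = 801, n_t = 8)
    for (ph in c(0, 0.3, 0.6)) {
      xy <- reconstruct_centerline(bp, ph)
      len <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
      expect_equal(len, 1, tolerance = 1e-4)
    }
  }
})

test_that("beat pattern validation rejects malformed inputs", {
  expect_error(beat_pattern(c(0, 0.5, 0.4), 0, matrix(0, 3, 1)),
               "strictly increasing")
  expect_error(beat_pattern(c(0.1, 0.5, 1), 0, matrix(0, 3, 1)), "start at 0")
  expect_error(beat_pattern(seq(0, 1, 0.5), c(0, 1.2), matrix(0, 3, 2)),
               "\\[0, 1\\)")
  # tangent pointing into the surface from the base
  expect_error(beat_pattern(seq(0, 1, 0.1), 0,
                            matrix(-pi / 3, 11, 1)), "penetrates")
  b <- beat_pattern(seq(0, 1, 0.5), 0, matrix(0.3, 3, 1))
  expect_error(reconstruct_centerline(b, 1.0), "phase")
  expect_error(reconstruct_centerline(b, -0.1), "phase")
})

test_that("mean tangent angle: constant case, oracle, and invariances", {
  s <- seq(0, 1, length.out = 51)
  const <- beat_pattern(s, c(0, 0.25, 0.5, 0.75),
                        matrix(53 * pi / 180, 51, 4))
  expect_equal(mean_tangent_angle(const), 53, tolerance = 1e-10)

  # asymmetric travelling wave psi = pi/2 - a s (1 + b sin 2 pi t) against a
  # dense-grid Riemann-sum oracle on the analytic form
  a <- 0.9; b <- 0.35
  psi_fun <- function(ss, tt) pi / 2 - a * ss * (1 + b * sin(2 * pi * tt))
  ns <- 101; nt <- 64
  sg <- seq(0, 1, length.out = ns)
  tg <- seq(0, 1 - 1 / nt, length.out = nt)
  bp <- beat_pattern(sg, tg, outer(sg, tg, psi_fun))
  so <- seq(0, 1, length.out = 4001)
  to <- seq(0, 1 - 1 / 2048, length.out = 2048)
  pp <- outer(so, to, psi_fun)
  ws <- rep(1, length(so)); ws[c(1, length(so))] <- 0.5
  ws <- ws / sum(ws)
  oracle <- atan2(sum(ws * rowMeans(sin(pp))), sum(ws * rowMeans(cos(pp)))) *
    180 / pi
  expect_equal(mean_tangent_angle(bp), oracle, tolerance = 1e-3)

  # invariant under time reversal and cyclic phase shifts
  rev_bp <- beat_pattern(sg, tg, bp$psi[, ncol(bp$psi):1][, c(64, 1:63)])
  expect_equal(mean_tangent_angle(rev_bp), mean_tangent_angle(bp),
               tolerance = 1e-10)
  shift <- beat_pattern(sg, tg, bp$psi[, c(17:64, 1:16)])
  expect_equal(mean_tangent_angle(shift), mean_tangent_angle(bp),
               tolerance = 1e-10)
})

test_that("swept summary reproduces the coarse-grained rod geometry", {
  s <- seq(0, 1, length.out = 51)
  rod53 <- beat_pattern(s, 0, matrix(53 * pi / 180, 51, 1))
  sm <- swept_summary(rod53, width = 0.08)
  expect_equal(sm$forward_angle, 53, tolerance = 1e-8)
  expect_equal(sm$backward_angle, 53, tolerance = 1e-8)
  expect_equal(sm$a_top, cos(53 * pi / 180) * 0.08, tolerance = 1e-8)

  # calibrated stroke extremes at 23 and 18 degrees
  cal <- calibrate_beat_extremes(23, 18)
  bp <- make_beat_pattern(cal$amplitude, cal$asymmetry, n_s = 201, n_t = 64)
  sm <- swept_summary(bp, width = 0.08)
  expect_equal(sm$forward_angle, 23, tolerance = 0.2)
  expect_equal(sm$backward_angle, 18, tolerance = 0.2)
  expect_equal(sm$a_top, (cos(23 * pi / 180) + cos(18 * pi / 180)) * 0.08,
               tolerance = 1e-3)
  expect_equal(sm$d_par_min, cos(23 * pi / 180) + cos(18 * pi / 180),
               tolerance = 1e-3)

  vertical <- beat_pattern(s, 0, matrix(pi / 2, 51, 1))
  expect_equal(swept_summary(vertical)$a_top, 0)
})

test_that("swept area grows with the sweep amplitude", {
  amps <- seq(0.4, 2.2, length.out = 7)
  atops <- vapply(amps, function(a)
    swept_summary(make_beat_pattern(a, 0, n_s = 101, n_t = 32))$a_top,
    numeric(1))
  expect_true(all(diff(atops) > 0))
})

test_that("beat patterns round-trip through CSV and JSON", {
  bp <- make_beat_pattern(1.2, 0.2, n_s = 15, n_t = 8)
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("beat.", ext))
    write_beat_pattern(bp, path)
    back <- read_beat_pattern(path)
    expect_equal(back$s_grid, bp$s_grid, tolerance = 1e-8)
    expect_equal(back$t_grid, bp$t_grid, tolerance = 1e-8)
    expect_equal(back$psi, bp$psi, tolerance = 1e-8)
    unlink(path)
  }
})
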