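test_that("activity map isolates oscillating pixels", {
  const <- movie(array(7, dim = c(8, 8, 10)), frame_rate = 100)
  sm <- activity_std_map(const)
  expect_true(all(sm == 0))
  expect_true(isTRUE(attr(sm, "constant")))

  stack <- array(5, dim = c(8, 8, 64))
  stack[3, 4, ] <- 5 + sin(2 * pi * seq_len(64) / 8)
  sm <- activity_std_map(movie(stack, 100))
  expect_equal(sm[3, 4], 1)
  expect_true(all(sm[-((4 - 1) * 8 + 3)] == 0))

  # normalised map preserves the std ratio of sampled sinusoids (closed
  # form: std of amplitude A sinusoid -> A / sqrt(2))
  stack <- array(0, dim = c(4, 4, 800))
  tt <- seq_len(800) / 160
  stack[1, 1, ] <- 2.0 * sin(2 * pi * 13 * tt)
  stack[2, 2, ] <- 1.0 * sin(2 * pi * 7 * tt + 0.3)
  sm <- activity_std_map(movie(stack, 160))
  expect_equal(sm[2, 2] / sm[1, 1], 0.5, tolerance = 0.02)
})

test_that("otsu mask matches a brute-force between-class-variance scan", {
  # two-delta histogram: threshold strictly between the modes
  m <- matrix(rep(c(0.1, 0.9), each = 128), 16, 16)
  mask <- otsu_mask(m)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  expect_equal(sum(mask), 128)

  # planted two-Gaussian map: misclassification below 2%, threshold close
  # to the independent scan oracle
  set.seed(5)
  truth <- matrix(runif(64 * 64) < 0.4, 64, 64)
  m <- matrix(rnorm(64 * 64, ifelse(truth, 0.75, 0.25), 0.07), 64, 64)
  m <- pmin(pmax(m, 0), 1)
  mask <- otsu_mask(m)
  expect_lt(mean(mask != truth), 0.02)
  expect_equal(attr(mask, "threshold"), otsu_scan_oracle(m), tolerance = 0.02)

  expect_warning(empty <- otsu_mask(matrix(0.5, 4, 4)), "degenerate")
  expect_true(all(!empty))
})

test_that("per-pixel beat frequency peaks at the planted frequency", {
  tt <- seq_len(800) / 160
  stack <- array(rnorm(16 * 16 * 800, 100, 1), dim = c(16, 16, 800))
  stack[2, 2, ] <- 100 + 10 * sin(2 * pi * 25 * tt)      # exact bin
  stack[3, 3, ] <- 100 + 10 * sin(2 * pi * 25.1 * tt)    # off-bin
  mov <- movie(stack, 160)
  mask <- matrix(FALSE, 16, 16); mask[2, 2] <- TRUE; mask[3, 3] <- TRUE
  cbf <- pixel_cbf(mov, mask)
  expect_equal(cbf$resolution, 0.2)
  expect_equal(cbf$frequency[2, 2], 25.0)
  expect_lte(abs(cbf$frequency[3, 3] - 25.1), 0.2)
  expect_true(cbf$confident[2, 2])
  expect_true(is.na(cbf$frequency[1, 1]))

  # pure-noise pixels are flagged low-confidence
  noise_mask <- matrix(TRUE, 16, 16)
  cbf_n <- pixel_cbf(movie(array(rnorm(16 * 16 * 800), dim = c(16, 16, 800)),
                           160), noise_mask)
  expect_lt(mean(cbf_n$confident), 0.2)

  expect_error(pixel_cbf(mov, mask, f_max = 90), "Nyquist")
})

test_that("segmentation splits touching patches with distinct frequencies", {
  f <- matrix(NA_real_, 20, 40)
  f[5:15, 5:18] <- 20
  f[5:15, 19:32] <- 30           # touching patch at a different frequency
  cbf <- structure(list(frequency = f, mask = !is.na(f),
                        confident = !is.na(f), resolution = 0.2),
                   class = "cbf_map")
  seg <- segment_ciliated_cells(cbf, sigma_f = 1, min_area = 20)
  expect_equal(seg$n_cells, 2L)
  expect_equal(sort(seg$cell_cbf), c(20, 30))
  # labels partition exactly along the frequency boundary
  expect_equal(length(unique(as.vector(seg$labels[5:15, 5:18]))), 1L)

  # homogeneous patch stays one cell
  f2 <- matrix(NA_real_, 20, 20); f2[4:16, 4:16] <- 24
  cbf2 <- structure(list(frequency = f2, mask = !is.na(f2),
                         confident = !is.na(f2), resolution = 0.2),
                    class = "cbf_map")
  expect_equal(segment_ciliated_cells(cbf2)$n_cells, 1L)
})

test_that("segmentation recovers planted cells under frequency jitter", {
  set.seed(21)
  spec <- synthetic_field_spec(fov_px = 240, n_cells = 12, cbf_sd = 3,
                               min_sep_factor = 1.3, seed = 21)
  lay <- make_field(spec)
  f <- matrix(NA_real_, 240, 240)
  idx <- which(lay$label_map > 0)
  f[idx] <- lay$cells$cbf_hz[lay$label_map[idx]] + rnorm(length(idx), 0, 0.3)
  cbf <- structure(list(frequency = f, mask = !is.na(f), confident = !is.na(f),
                        resolution = 0.2), class = "cbf_map")
  seg <- segment_ciliated_cells(cbf, sigma_f = 1, min_area = 20)
  expect_equal(seg$n_cells, 12L)
})

test_that("PIV recovers rigid translation exactly and zero motion as zero", {
  set.seed(3)
  # particle texture periodic with the window, so an integer shift is an
  # exact circular shift inside every interrogation box
  w <- 32
  tile <- matrix(0, w, w)
  cx <- runif(40, 0, w); cy <- runif(40, 0, w)
  for (p in 1:40) {
    gx <- exp(-pmin(abs(1:w - cx[p]), w - abs(1:w - cx[p]))^2 / 3)
    gy <- exp(-pmin(abs(1:w - cy[p]), w - abs(1:w - cy[p]))^2 / 3)
    tile <- tile + outer(gy, gx)
  }
  base <- rbind(cbind(tile, tile), cbind(tile, tile))
  # shift 2 px along +x per frame (columns), circularly
  shift2 <- function(m, k) m[, ((seq_len(ncol(m)) - 1 - k) %% ncol(m)) + 1]
  stack <- array(0, dim = c(64, 64, 5))
  for (k in 1:5) stack[, , k] <- shift2(base, 2 * (k - 1))
  mov <- movie(stack, frame_rate = 1, pixel_size = 1)
  for (avg in c("correlation", "displacement")) {
    fl <- piv(mov, window = 32, average = avg)
    expect_lt(max(abs(fl$vx - 2)), 0.1)
    expect_lt(max(abs(fl$vy)), 0.1)
  }

  still <- movie(array(rep(base, 4), dim = c(64, 64, 4)), 1, 1)
  fl0 <- piv(still, window = 32)
  expect_lt(max(abs(c(fl0$vx, fl0$vy))), 1e-6)
})

test_that("PIV recovers a planted Poiseuille-like profile", {
  # vx(y) parabolic across the field, vy = 0; rendered with an independent
  # particle advection oracle
  fov <- 128; vmax <- 8
  flow <- function(px, py) {
    cbind(vmax * 4 * (py / fov) * (1 - py / fov), 0)
  }
  mov <- advect_particles_movie(flow, fov, n_frames = 60, frame_rate = 10,
                                brownian_sd_px = 0.3, resample_frac = 0.05,
                                seed = 8)
  fl <- piv(mov)
  truth <- flow((col(fl$vx) - 0.5) * 32, (row(fl$vx) - 0.5) * 32)
  rmse <- sqrt(mean((fl$vx - truth[, 1])^2 + fl$vy^2, na.rm = TRUE))
  expect_lt(rmse / vmax, 0.10)
})

test_that("cell records merge labels, frequencies and flow per box", {
  # one cell exactly filling one interrogation box
  lab <- matrix(0L, 64, 64); lab[33:64, 1:32] <- 1L
  labels <- structure(list(labels = lab, n_cells = 1L, cell_cbf = 24),
                      class = "cell_label_map")
  f <- matrix(NA_real_, 64, 64); f[lab == 1L] <- 24
  cbf <- structure(list(frequency = f, mask = lab > 0, confident = lab > 0,
                        resolution = 0.2), class = "cbf_map")
  flow <- structure(list(
    vx = matrix(c(0, 3, 0, 4), 2, 2), vy = matrix(c(0, 4, 0, 0), 2, 2),
    valid = matrix(TRUE, 2, 2), window = 32L, n_pairs = 9L,
    pixel_size = 0.2375, x_um = c(16, 48) * 0.2375,
    y_um = c(16, 48) * 0.2375), class = "flow_field")
  rec <- cells_to_boxes(labels, flow, cbf)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$box_i, 2L); expect_equal(rec$box_j, 1L)
  expect_equal(rec$cbf_hz, 24)
  expect_equal(c(rec$px, rec$py), c(3, 4) / 5)
  expect_equal(attr(rec, "n_boxes_total"), 4L)

  # no ciliated boxes -> empty record set
  labels0 <- structure(list(labels = matrix(0L, 64, 64), n_cells = 0L,
                            cell_cbf = numeric(0)), class = "cell_label_map")
  rec0 <- cells_to_boxes(labels0, flow, cbf)
  expect_equal(nrow(rec0), 0L)
})

test_that("pipeline output is invariant under global intensity rescaling", {
  spec <- synthetic_field_spec(fov_px = 128, n_cells = 3, seed = 4)
  lay <- make_field(spec)
  bf <- render_bf_movie(lay, n_frames = 256)
  tr <- render_tracer_movie(lay, synthetic_tracer_spec(n_frames = 30))
  res1 <- analyze_fov(bf, tr)
  bf2 <- movie(3.7 * bf$stack + 12, bf$frame_rate, bf$pixel_size)
  tr2 <- movie(2.1 * tr$stack - 1, tr$frame_rate, tr$pixel_size)
  res2 <- analyze_fov(bf2, tr2)
  expect_equal(res1$labels$labels, res2$labels$labels)
  expect_equal(res1$records$cbf_hz, res2$records$cbf_hz)
  expect_equal(res1$records$vx_um_s, res2$records$vx_um_s, tolerance = 1e-6)
})

test_that("rotating both movies rotates the recovered directions", {
  spec <- synthetic_field_spec(fov_px = 128, n_cells = 3, seed = 6)
  lay <- make_field(spec)
  bf <- render_bf_movie(lay, n_frames = 256)
  tr <- render_tracer_movie(lay, synthetic_tracer_spec(n_frames = 30))
  res <- analyze_fov(bf, tr)
  rot90 <- function(mov) {
    d <- dim(mov$stack)
    rs <- array(0, dim = c(d[2], d[1], d[3]))
    for (k in seq_len(d[3]))
      rs[, , k] <- t(mov$stack[, , k])[, d[1]:1]      # 90 deg ccw in (x, y)
    movie(rs, mov$frame_rate, mov$pixel_size)
  }
  res_r <- analyze_fov(rot90(bf), rot90(tr))
  expect_equal(nrow(res_r$records), nrow(res$records))
  a0 <- sort(round(atan2(res$records$py, res$records$px), 2))
  # the frame rotation maps every vector angle to angle + pi/2
  a1 <- atan2(res_r$records$py, res_r$records$px)
  a1_back <- sort(round(((a1 - pi / 2 + pi) %% (2 * pi)) - pi, 2))
  expect_equal(length(a0), length(a1_back))
  expect_lt(max(abs(a0 - a1_back)), 0.1)
})

test_that("drift between stacks is estimated and gates the pipeline", {
  set.seed(9)
  base <- matrix(rnorm(96 * 96), 96, 96)
  sm <- function(m) {
    k <- matrix(1 / 9, 3, 3)
    out <- m
    for (i in 2:95) for (j in 2:95) out[i, j] <- mean(m[(i - 1):(i + 1), (j - 1):(j + 1)])
    out
  }
  base <- sm(base)
  shifted <- base[c(4:96, 1:3), c(6:96, 1:5)]      # dy = -3, dx = -5
  mov_a <- movie(array(rep(base, 3), dim = c(96, 96, 3)), 10)
  mov_b <- movie(array(rep(shifted, 3), dim = c(96, 96, 3)), 10)
  dr <- estimate_drift(mov_a, mov_b)
  expect_equal(unname(abs(dr)), c(5, 3))
  expect_error(analyze_fov(mov_a, mov_b, check_drift = TRUE), "drift")
})

test_that("movies round-trip through multi-page TIFF with metadata", {
  spec <- synthetic_field_spec(fov_px = 64, n_cells = 2, seed = 3)
  mov <- render_bf_movie(make_field(spec), n_frames = 6)
  path <- file.path(tempdir(), "mov.tif")
  meta <- file.path(tempdir(), "mov.json")
  write_movie(mov, path)
  jsonlite::write_json(list(frame_rate = 160, pixel_size = 0.2375), meta,
                       auto_unbox = TRUE)
  back <- read_movie(path, meta = meta)
  expect_equal(dim(back$stack), dim(mov$stack))
  expect_equal(back$frame_rate, 160)
  # 16-bit quantisation after min-max rescale
  rng <- range(mov$stack)
  expect_equal(back$stack, (mov$stack - rng[1]) / diff(rng),
               tolerance = 1e-4)
  unlink(c(path, meta))
})
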