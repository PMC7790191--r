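# shared fixtures and independent oracles, built in code at test time

# absolute angular difference in degrees, wrapped to [0, 180]
ang_err_deg <- function(a, b) {
  abs((((a - b) + pi) %% (2 * pi)) - pi) * 180 / pi
}

# high-resolution trapezoidal quadrature oracle for the centreline tip of a
# tangent-angle function psi(s) (independent of the package's cumtrapz path)
tip_oracle <- function(psi_fun, n = 1e5) {
  s <- seq(0, 1, length.out = n + 1)
  p <- psi_fun(s)
  dy <- diff(s) * (cos(p[-1]) + cos(p[-(n + 1)])) / 2
  dz <- diff(s) * (sin(p[-1]) + sin(p[-(n + 1)])) / 2
  c(y = sum(dy), z = sum(dz))
}

# brute-force Otsu oracle: scan all 256-bin thresholds for the maximum
# between-class variance
otsu_scan_oracle <- function(x, levels = 256) {
  h <- tabulate(pmin(floor(x * levels) + 1, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; thr <- NA
  for (k in 1:(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- mids[k] + 0.5 / levels }
  }
  thr
}

# render a movie of Gaussian particles advected by an arbitrary velocity
# field (um/s); independent of the package's tracer generator
advect_particles_movie <- function(flow_fun, fov_px, n_frames, frame_rate,
                                   pixel_size = 0.2375, n_particles = NULL,
                                   brownian_sd_px = 0, resample_frac = 0,
                                   seed = 1) {
  set.seed(seed)
  n <- fov_px
  np <- n_particles %||% ceiling(10 * (n / 32)^2)
  px <- runif(np, 1, n); py <- runif(np, 1, n)
  sig <- 1.5; halo <- 5
  stack <- array(rnorm(n * n * n_frames, 0, 2), dim = c(n, n, n_frames))
  dt <- 1 / frame_rate
  for (k in seq_len(n_frames)) {
    frame <- matrix(0, n, n)
    for (p in seq_len(np)) {
      c0 <- max(1L, floor(px[p]) - halo); c1 <- min(n, ceiling(px[p]) + halo)
      r0 <- max(1L, floor(py[p]) - halo); r1 <- min(n, ceiling(py[p]) + halo)
      xs <- c0:c1; ys <- r0:r1
      frame[ys, xs] <- frame[ys, xs] +
        200 * outer(exp(-(ys - py[p])^2 / (2 * sig^2)),
                    exp(-(xs - px[p])^2 / (2 * sig^2)))
    }
    stack[, , k] <- stack[, , k] + frame
    v <- flow_fun(px, py)
    px <- ((px + v[, 1] / pixel_size * dt +
              rnorm(np, 0, brownian_sd_px) - 1) %% n) + 1
    py <- ((py + v[, 2] / pixel_size * dt +
              rnorm(np, 0, brownian_sd_px) - 1) %% n) + 1
    if (resample_frac > 0) {
      ridx <- which(runif(np) < resample_frac)
      px[ridx] <- runif(length(ridx), 1, n)
      py[ridx] <- runif(length(ridx), 1, n)
    }
  }
  movie(stack, frame_rate, pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-record direction error (degrees) against the dominant planted cell
record_direction_errors <- function(records, layout, window = 32L) {
  vapply(seq_len(nrow(records)), function(k) {
    rows <- ((records$box_i[k] - 1) * window + 1):(records$box_i[k] * window)
    cols <- ((records$box_j[k] - 1) * window + 1):(records$box_j[k] * window)
    sub <- layout$label_map[rows, cols]
    sub <- sub[sub > 0]
    cell <- as.integer(names(which.max(table(sub))))
    ang_err_deg(atan2(records$py[k], records$px[k]),
                layout$cells$dir_rad[cell])
  }, numeric(1))
}

# median recovered beat frequency over each planted cell's pixels
recovered_cell_cbf <- function(cbf_map, layout) {
  vapply(seq_len(nrow(layout$cells)), function(i) {
    stats::median(cbf_map$frequency[layout$label_map == i], na.rm = TRUE)
  }, numeric(1))
}
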