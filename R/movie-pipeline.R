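#' Microscopy movie container
#'
#' A movie is an intensity stack with acquisition metadata. Stacks are stored
#' as `rows x cols x frames` arrays. Bright-field recordings of beating cilia
#' are typically acquired at 160 frames/s for 5 s; tracer (fluorescence)
#' recordings at 10 frames/s for 10 s on the same field of view.
#'
#' @param stack numeric array `rows x cols x frames` (at least 2 frames).
#' @param frame_rate acquisition rate, Hz.
#' @param pixel_size pixel size, micrometres per pixel. The default 0.2375
#'   makes a 32-pixel interrogation box 7.6 um across.
#' @return An object of class `movie`.
#' @export
movie <- function(stack, frame_rate, pixel_size = 0.2375) {
  stack <- as.array(stack)
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    stop_domain("stack must be a rows x cols x frames array with >= 2 frames")
  stopifnot(frame_rate > 0, pixel_size > 0)
  structure(list(stack = stack, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Movie: %d x %d px, %d frames at %g fps (%.3g um/px)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Read / write movies as multi-page TIFF
#'
#' `read_movie()` loads a multi-page TIFF stack; metadata (`frame_rate`,
#' `pixel_size`) come from the arguments or from a JSON sidecar with those
#' fields. `write_movie()` writes one page per frame, linearly rescaled to
#' `[0, 1]` as 16-bit.
#'
#' @param path TIFF file path.
#' @param frame_rate,pixel_size acquisition metadata (override the sidecar).
#' @param meta optional path to a JSON file with `frame_rate` and
#'   `pixel_size` fields.
#' @return `read_movie()` returns a [movie()]; `write_movie()` the path,
#'   invisibly.
#' @export
read_movie <- function(path, frame_rate = NULL, pixel_size = NULL, meta = NULL) {
  if (!is.null(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    frame_rate <- frame_rate %||% m$frame_rate
    pixel_size <- pixel_size %||% m$pixel_size
  }
  if (is.null(frame_rate))
    stop_domain("frame_rate must be given directly or via a metadata file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
  movie(stack, frame_rate, pixel_size %||% 0.2375)
}

#' @rdname read_movie
#' @param mov a [movie()].
#' @export
write_movie <- function(mov, path) {
  stopifnot(inherits(mov, "movie"))
  rng <- range(mov$stack)
  denom <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(seq_len(dim(mov$stack)[3]), function(k)
    (mov$stack[, , k] - rng[1]) / denom)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Temporal-activity map of a movie
#'
#' Computes the per-pixel standard deviation of intensity over time and
#' min-max normalises it to `[0, 1]`. Beating cilia produce strong intensity
#' fluctuations, so this map highlights ciliated regions. A perfectly
#' constant movie yields an all-zero map, flagged with the attribute
#' `constant = TRUE`.
#'
#' @param mov a [movie()].
#' @return A `rows x cols` matrix in `[0, 1]`.
#' @export
activity_std_map <- function(mov) {
  stopifnot(inherits(mov, "movie"))
  d <- dim(mov$stack)
  n <- d[3]
  m <- matrix(mov$stack, d[1] * d[2], n)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  s <- matrix(sqrt(pmax(v, 0)), d[1], d[2])
  rng <- range(s)
  if (diff(rng) == 0) {
    out <- matrix(0, d[1], d[2])
    attr(out, "constant") <- TRUE
    return(out)
  }
  (s - rng[1]) / diff(rng)
}

#' Otsu threshold mask of an activity map
#'
#' Thresholds a `[0, 1]` map with Otsu's method (256-bin histogram,
#' maximising the between-class variance) and returns the above-threshold
#' mask. A degenerate single-valued map yields an empty mask with a warning.
#'
#' @param std_map matrix in `[0, 1]`, e.g. from [activity_std_map()].
#' @return Logical matrix; `TRUE` for active (above-threshold) pixels. The
#'   threshold is attached as attribute `threshold`.
#' @export
otsu_mask <- function(std_map) {
  stopifnot(is.matrix(std_map))
  if (min(std_map) < 0 || max(std_map) > 1)
    stop_domain("std_map must lie in [0, 1]")
  if (diff(range(std_map)) == 0) {
    warning("degenerate single-valued map: empty mask")
    out <- matrix(FALSE, nrow(std_map), ncol(std_map))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- EBImage::otsu(std_map, range = c(0, 1), levels = 256)
  out <- std_map > thr
  attr(out, "threshold") <- thr
  out
}

#' Per-pixel ciliary beat frequency map
#'
#' For every masked pixel, takes the magnitude spectrum of its intensity
#' time series and reports the frequency of the highest peak within the
#' physiological band (DC excluded). The spectral resolution is
#' `frame_rate / n_frames` (0.2 Hz for 160 fps x 5 s). Pixels whose peak is
#' not prominent (peak magnitude below `min_prominence` times the median
#' in-band magnitude) are flagged low-confidence.
#'
#' @param mov a [movie()].
#' @param mask logical matrix of pixels to analyse (e.g. from
#'   [otsu_mask()]); `NULL` analyses every pixel.
#' @param f_min,f_max frequency band, Hz (default 1-50). `f_max` must be
#'   below the Nyquist frequency.
#' @param min_prominence peak-to-median magnitude ratio below which a pixel
#'   is flagged low-confidence.
#' @return A list of class `cbf_map`: `frequency` (matrix, Hz, `NA` outside
#'   the mask), `mask`, `confident` (logical matrix), `resolution` (Hz).
#' @export
pixel_cbf <- function(mov, mask = NULL, f_min = 1, f_max = 50,
                      min_prominence = 5) {
  stopifnot(inherits(mov, "movie"))
  d <- dim(mov$stack)
  nf <- d[3]
  if (f_max >= mov$frame_rate / 2)
    stop_domain(sprintf("band maximum %.1f Hz is not below Nyquist (%.1f Hz)",
                        f_max, mov$frame_rate / 2))
  if (f_min <= 0 || f_min >= f_max) stop_domain("need 0 < f_min < f_max")
  mask <- mask %||% matrix(TRUE, d[1], d[2])
  idx <- which(mask)
  if (length(idx) == 0L) stop_domain("mask selects no pixels")
  m <- matrix(mov$stack, d[1] * d[2], nf)[idx, , drop = FALSE]
  spec <- Mod(mvfft(t(m)))                      # frames x pixels
  freqs <- (seq_len(nf) - 1) * mov$frame_rate / nf
  band <- which(freqs >= f_min & freqs <= f_max)
  if (length(band) == 0L) stop_domain("frequency band contains no FFT bins")
  sb <- spec[band, , drop = FALSE]
  peak <- band[apply(sb, 2L, which.max)]
  pk <- apply(sb, 2L, max)
  md <- apply(sb, 2L, median)
  fmat <- matrix(NA_real_, d[1], d[2])
  fmat[idx] <- freqs[peak]
  conf <- matrix(FALSE, d[1], d[2])
  conf[idx] <- pk >= min_prominence * pmax(md, .Machine$double.eps)
  structure(list(frequency = fmat, mask = mask, confident = conf,
                 resolution = mov$frame_rate / nf),
            class = "cbf_map")
}

# 8-connected neighbour offsets
neighbours8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                     dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Segment multiciliated cells from a beat-frequency map
#'
#' Groups geometrically connected validated pixels (8-connectivity) into
#' cells by region growing: a neighbouring pixel joins a component only
#' while the component's frequency standard deviation stays at or below
#' `sigma_f` and the pixel's own frequency lies within `max_dev_factor *
#' sigma_f` of the component mean (without the per-pixel gate a large
#' homogeneous component could swallow a touching patch one boundary pixel
#' at a time, since a single outlier barely moves the standard deviation).
#' Touching patches beating at clearly different frequencies are therefore
#' split. Components smaller than `min_area` pixels are dropped.
#'
#' @param cbf a `cbf_map` from [pixel_cbf()].
#' @param sigma_f within-cell frequency standard-deviation cap, Hz. The
#'   default 1.0 Hz sits above the spectral resolution (0.2 Hz at
#'   160 fps x 5 s) and below typical between-cell frequency differences.
#' @param min_area minimum component size, pixels.
#' @param max_dev_factor per-pixel admission gate, in units of `sigma_f`.
#' @param confident_only use only pixels flagged confident in `cbf`.
#' @return A list of class `cell_label_map`: `labels` (integer matrix, 0 =
#'   background), `n_cells`, and per-cell mean frequencies `cell_cbf`.
#' @export
segment_ciliated_cells <- function(cbf, sigma_f = 1.0, min_area = 20,
                                   max_dev_factor = 2,
                                   confident_only = FALSE) {
  stopifnot(inherits(cbf, "cbf_map"), sigma_f > 0)
  f <- cbf$frequency
  valid <- !is.na(f)
  if (confident_only) valid <- valid & cbf$confident
  nr <- nrow(f); nc <- ncol(f)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  sums <- numeric(0); sqs <- numeric(0); cnt <- integer(0)
  for (start in which(valid & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    # BFS with an incremental variance bound
    queue <- start
    qh <- 1L
    labels[start] <- lab
    s1 <- f[start]; s2 <- f[start]^2; n1 <- 1L
    while (qh <= length(queue)) {
      p <- queue[qh]; qh <- qh + 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(8L)) {
        r <- pr + neighbours8[k, 1L]; cl <- pc + neighbours8[k, 2L]
        if (r < 1L || r > nr || cl < 1L || cl > nc) next
        q <- (cl - 1L) * nr + r
        if (!valid[q] || labels[q] != 0L) next
        if (abs(f[q] - s1 / n1) > max_dev_factor * sigma_f) next
        ns1 <- s1 + f[q]; ns2 <- s2 + f[q]^2; nn <- n1 + 1L
        sdn <- sqrt(max(0, (ns2 - ns1^2 / nn) / (nn - 1L)))
        if (sdn <= sigma_f) {
          labels[q] <- lab
          s1 <- ns1; s2 <- ns2; n1 <- nn
          queue[length(queue) + 1L] <- q
        }
      }
    }
    sums[lab] <- s1; sqs[lab] <- s2; cnt[lab] <- n1
  }
  # drop small components, relabel compactly
  keep <- which(cnt >= min_area)
  remap <- integer(lab)
  remap[keep] <- seq_along(keep)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  structure(list(labels = labels, n_cells = length(keep),
                 cell_cbf = if (length(keep)) sums[keep] / cnt[keep] else numeric(0)),
            class = "cell_label_map")
}

# subpixel displacement of the cross-correlation peak (3-point Gaussian fit)
gauss_subpixel <- function(cm, c0, cp) {
  if (cm <= 0 || c0 <= 0 || cp <= 0) return(0)
  den <- log(cm) + log(cp) - 2 * log(c0)
  if (den >= 0) return(0)
  0.5 * (log(cm) - log(cp)) / den
}

#' Particle image velocimetry on a tracer movie
#'
#' One-pass PIV: the field of view is tiled with non-overlapping square
#' interrogation boxes; for every pair of consecutive frames, each box of
#' frame `t` is cross-correlated (FFT, mean-subtracted and normalised) with
#' the same box of frame `t + 1`. The frame pairs are combined either by
#' ensemble-averaging the correlation planes before locating the peak
#' (`average = "correlation"`, the default -- robust for a steady flow with
#' sparse tracers, where single-pair peaks are noisy) or by averaging the
#' per-pair peak displacements (`average = "displacement"`). The peak is
#' refined to sub-pixel precision by a 3-point Gaussian fit and converted to
#' um/s with the frame rate and pixel size. Boxes without texture
#' (near-zero variance) are marked invalid and excluded.
#'
#' @param mov a tracer [movie()].
#' @param window interrogation box size, pixels (default 32, i.e. 7.6 um at
#'   the default pixel size).
#' @param average how frame pairs are combined (see above).
#' @param min_sd minimum within-box intensity standard deviation for a frame
#'   pair to count.
#' @return A list of class `flow_field`: matrices `vx`, `vy` (um/s, box
#'   grid, oriented row = image row block), `valid`, `window`, `n_pairs`,
#'   `pixel_size`, grid box centres `x_um`, `y_um`.
#' @export
piv <- function(mov, window = 32L, average = c("correlation", "displacement"),
                min_sd = 1e-6) {
  average <- match.arg(average)
  stopifnot(inherits(mov, "movie"), window >= 8)
  d <- dim(mov$stack)
  nbr <- d[1] %/% window
  nbc <- d[2] %/% window
  if (nbr < 1L || nbc < 1L) stop_domain("movie smaller than one interrogation box")
  nf <- d[3]
  sx <- matrix(0, nbr, nbc); sy <- matrix(0, nbr, nbc)
  cntm <- matrix(0L, nbr, nbc)
  ccsum <- if (average == "correlation")
    array(0, dim = c(window, window, nbr, nbc)) else NULL
  half <- window / 2
  wrap <- function(i) ((i - 1L) %% window) + 1L
  peak_of <- function(cc) {
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dr <- pk[1] - 1L; if (dr >= half) dr <- dr - window
    dcl <- pk[2] - 1L; if (dcl >= half) dcl <- dcl - window
    subr <- gauss_subpixel(cc[wrap(pk[1] - 1L), pk[2]], cc[pk[1], pk[2]],
                           cc[wrap(pk[1] + 1L), pk[2]])
    subc <- gauss_subpixel(cc[pk[1], wrap(pk[2] - 1L)], cc[pk[1], pk[2]],
                           cc[pk[1], wrap(pk[2] + 1L)])
    c(dr + subr, dcl + subc)
  }
  for (t in seq_len(nf - 1L)) {
    a_full <- mov$stack[, , t]
    b_full <- mov$stack[, , t + 1L]
    for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
      rows <- ((bi - 1L) * window + 1L):(bi * window)
      cols <- ((bj - 1L) * window + 1L):(bj * window)
      a <- a_full[rows, cols]; b <- b_full[rows, cols]
      sda <- sd(a); sdb <- sd(b)
      if (!is.finite(sda) || !is.finite(sdb) || sda < min_sd || sdb < min_sd)
        next
      a <- (a - mean(a)) / sda
      b <- (b - mean(b)) / sdb
      cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)
      if (average == "correlation") {
        ccsum[, , bi, bj] <- ccsum[, , bi, bj] + cc
      } else {
        dsp <- peak_of(cc)
        sy[bi, bj] <- sy[bi, bj] + dsp[1]      # displacement along rows
        sx[bi, bj] <- sx[bi, bj] + dsp[2]      # displacement along cols
      }
      cntm[bi, bj] <- cntm[bi, bj] + 1L
    }
  }
  valid <- cntm > 0L
  if (average == "correlation") {
    for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
      if (!valid[bi, bj]) next
      dsp <- peak_of(ccsum[, , bi, bj] / cntm[bi, bj])
      sy[bi, bj] <- dsp[1] * cntm[bi, bj]      # reuse the mean-divide below
      sx[bi, bj] <- dsp[2] * cntm[bi, bj]
    }
  }
  scale <- mov$frame_rate * mov$pixel_size     # px/frame -> um/s
  vx <- ifelse(valid, sx / pmax(cntm, 1L) * scale, NA_real_)
  vy <- ifelse(valid, sy / pmax(cntm, 1L) * scale, NA_real_)
  structure(list(vx = vx, vy = vy, valid = valid, window = as.integer(window),
                 n_pairs = nf - 1L, pixel_size = mov$pixel_size,
                 x_um = (seq_len(nbc) - 0.5) * window * mov$pixel_size,
                 y_um = (seq_len(nbr) - 0.5) * window * mov$pixel_size),
            class = "flow_field")
}

#' Rigid-drift estimate between two movies of the same field
#'
#' Cross-correlates the (mean-subtracted) temporal-mean frames of the two
#' stacks and returns the peak lag in pixels. Meaningful only for
#' same-modality recordings; large drift between the bright-field and tracer
#' acquisitions invalidates the per-cell pairing of beat frequency and
#' direction.
#'
#' @param mov_a,mov_b two [movie()]s of identical frame size.
#' @return Named numeric `c(dx, dy)` (column, row lag in pixels).
#' @export
estimate_drift <- function(mov_a, mov_b) {
  a <- apply(mov_a$stack, c(1, 2), mean)
  b <- apply(mov_b$stack, c(1, 2), mean)
  if (!all(dim(a) == dim(b))) stop_domain("movies differ in frame size")
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dr <- pk[1] - 1L; if (dr >= nrow(a) / 2) dr <- dr - nrow(a)
  dcl <- pk[2] - 1L; if (dcl >= ncol(a) / 2) dcl <- dcl - ncol(a)
  c(dx = dcl, dy = dr)
}

#' Merge cell labels, beat frequencies and flow into per-cell records
#'
#' The field of view is divided into the PIV interrogation boxes. A box
#' becomes a cell record when at least `min_frac` of its pixels belong to a
#' segmented ciliated cell and its PIV vector is valid and non-zero. Each
#' record carries the box indices, the box-centre position (um), the mean
#' beat frequency over the ciliated pixels in the box, the PIV velocity
#' (um/s), and the unit beating direction inferred from the flow.
#'
#' @param labels a `cell_label_map` from [segment_ciliated_cells()].
#' @param flow a `flow_field` from [piv()] on the matching tracer movie.
#' @param cbf the `cbf_map` used for segmentation.
#' @param min_frac minimum ciliated-pixel fraction per box (default 0.1).
#' @return A `data.frame` of class `cell_records` with columns `box_i`,
#'   `box_j`, `x_um`, `y_um`, `cbf_hz`, `vx_um_s`, `vy_um_s`, `px`, `py`.
#'   Attributes: `n_boxes_total`, `n_boxes_ciliated` (boxes passing the
#'   ciliated-fraction rule), `n_zero_velocity` (ciliated boxes dropped for
#'   missing/zero flow), `a_box_um2`.
#' @export
cells_to_boxes <- function(labels, flow, cbf, min_frac = 0.1) {
  stopifnot(inherits(labels, "cell_label_map"), inherits(flow, "flow_field"),
            inherits(cbf, "cbf_map"))
  w <- flow$window
  lab <- labels$labels
  nbr <- nrow(flow$vx); nbc <- ncol(flow$vx)
  if (nbr * w > nrow(lab) || nbc * w > ncol(lab))
    stop_domain("flow grid does not fit the label map")
  rec <- vector("list", nbr * nbc)
  n_cil <- 0L; n_zero <- 0L; ri <- 0L
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    rows <- ((bi - 1L) * w + 1L):(bi * w)
    cols <- ((bj - 1L) * w + 1L):(bj * w)
    sub <- lab[rows, cols]
    frac <- mean(sub > 0L)
    if (frac < min_frac) next
    n_cil <- n_cil + 1L
    vx <- flow$vx[bi, bj]; vy <- flow$vy[bi, bj]
    if (!flow$valid[bi, bj] || !is.finite(vx) || !is.finite(vy) ||
        (vx == 0 && vy == 0)) {
      n_zero <- n_zero + 1L
      next
    }
    fr <- cbf$frequency[rows, cols]
    mhz <- mean(fr[sub > 0L], na.rm = TRUE)
    sp <- sqrt(vx^2 + vy^2)
    ri <- ri + 1L
    rec[[ri]] <- data.frame(
      box_i = bi, box_j = bj,
      x_um = flow$x_um[bj], y_um = flow$y_um[bi],
      cbf_hz = mhz, vx_um_s = vx, vy_um_s = vy,
      px = vx / sp, py = vy / sp)
  }
  out <- if (ri > 0L) do.call(rbind, rec[seq_len(ri)]) else
    data.frame(box_i = integer(0), box_j = integer(0), x_um = numeric(0),
               y_um = numeric(0), cbf_hz = numeric(0), vx_um_s = numeric(0),
               vy_um_s = numeric(0), px = numeric(0), py = numeric(0))
  class(out) <- c("cell_records", "data.frame")
  attr(out, "n_boxes_total") <- nbr * nbc
  attr(out, "n_boxes_ciliated") <- n_cil
  attr(out, "n_zero_velocity") <- n_zero
  attr(out, "a_box_um2") <- (w * flow$pixel_size)^2
  out
}

#' Analyse one field of view end to end
#'
#' Chains the full pipeline: activity map and Otsu mask on the bright-field
#' movie, per-pixel beat frequency, cell segmentation, PIV on the tracer
#' movie, and the merge into per-cell records. When `check_drift = TRUE`
#' the two stacks are first registered by mean-frame cross-correlation and
#' the pipeline stops if the drift exceeds `max_drift_px` (only meaningful
#' for same-modality stacks; synthetic bright-field and tracer movies share
#' no texture, so the check defaults to off).
#'
#' @param bf bright-field [movie()].
#' @param fl tracer [movie()].
#' @param f_min,f_max beat-frequency band, Hz.
#' @param sigma_f,min_area segmentation parameters, see
#'   [segment_ciliated_cells()].
#' @param window PIV box size, pixels.
#' @param min_frac box ciliated-fraction rule, see [cells_to_boxes()].
#' @param check_drift,max_drift_px registration check.
#' @return A list with `records` ([cells_to_boxes()] output), `cbf`,
#'   `labels`, `flow`, `mask`.
#' @export
analyze_fov <- function(bf, fl, f_min = 1, f_max = 50, sigma_f = 1.0,
                        min_area = 20, window = 32L, min_frac = 0.1,
                        check_drift = FALSE, max_drift_px = 2) {
  if (check_drift) {
    dr <- estimate_drift(bf, fl)
    if (max(abs(dr)) > max_drift_px)
      stop_domain(sprintf(
        "drift between stacks is (%g, %g) px, above the %g px limit",
        dr["dx"], dr["dy"], max_drift_px))
  }
  sm <- activity_std_map(bf)
  mask <- otsu_mask(sm)
  cbf <- pixel_cbf(bf, mask, f_min = f_min, f_max = f_max)
  labels <- segment_ciliated_cells(cbf, sigma_f = sigma_f, min_area = min_area)
  flow <- piv(fl, window = window)
  records <- cells_to_boxes(labels, flow, cbf, min_frac = min_frac)
  list(records = records, cbf = cbf, labels = labels, flow = flow, mask = mask)
}

#' Write per-cell records to CSV
#'
#' @param records a `cell_records` data frame.
#' @param path output CSV path.
#' @param fov optional field-of-view identifier column.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path, fov = NA) {
  df <- cbind(fov = fov, as.data.frame(records))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
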