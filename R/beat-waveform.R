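#' Planar cilia beat pattern
#'
#' A beat pattern stores the tangent-angle profile \eqn{\psi(s, t)} of the
#' cilium centreline on an arclength-by-phase grid. The arclength fraction
#' \eqn{s \in [0, 1]} is measured in units of the cilium length \eqn{L}, the
#' phase \eqn{t \in [0, 1)} covers one beat period, and \eqn{\psi} is the
#' angle of the local tangent measured from the in-plane beating direction
#' \eqn{\hat e} towards the surface normal \eqn{\hat z}. The beat is planar:
#' every tangent lies in the \eqn{\hat e}-\eqn{\hat z} plane.
#'
#' @param s_grid numeric, strictly increasing arclength fractions starting
#'   at 0, in units of the cilium length.
#' @param t_grid numeric, strictly increasing phase samples in `[0, 1)`.
#' @param psi numeric matrix `length(s_grid)` x `length(t_grid)` of tangent
#'   angles in radians, each in `(-pi, pi]`.
#'
#' @return An object of class `beat_pattern`.
#' @examples
#' b <- beat_pattern(seq(0, 1, length.out = 11), 0, matrix(pi / 4, 11, 1))
#' mean_tangent_angle(b)
#' @export
beat_pattern <- function(s_grid, t_grid, psi) {
  s_grid <- as.numeric(s_grid)
  t_grid <- as.numeric(t_grid)
  psi <- matrix(as.numeric(psi), length(s_grid), length(t_grid))
  obj <- structure(list(s_grid = s_grid, t_grid = t_grid, psi = psi),
                   class = "beat_pattern")
  validate_beat_pattern(obj)
  obj
}

#' Validate a beat pattern
#'
#' Checks grid monotonicity, the angle range, and that the centreline
#' reconstructed from \eqn{\psi} never penetrates the surface
#' (\eqn{z(s,t) \ge 0} at every sample, up to quadrature tolerance).
#'
#' @param beat a [beat_pattern()].
#' @param tol tolerance on surface penetration, in units of \eqn{L}.
#' @return `beat`, invisibly; errors on an invalid object.
#' @export
validate_beat_pattern <- function(beat, tol = 1e-8) {
  s <- beat$s_grid; t <- beat$t_grid; psi <- beat$psi
  if (length(s) < 1L || length(t) < 1L)
    stop_domain("beat pattern grids must be non-empty")
  if (abs(s[1]) > .Machine$double.eps)
    stop_domain("s_grid must start at 0")
  if (length(s) > 1L && any(diff(s) <= 0))
    stop_domain("s_grid must be strictly increasing")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_domain("t_grid must be strictly increasing")
  if (any(t < 0 | t >= 1))
    stop_domain("t_grid must lie in [0, 1)")
  if (!all(is.finite(psi)))
    stop_domain("psi contains non-finite values")
  if (any(psi <= -pi | psi > pi))
    stop_domain("psi must lie in (-pi, pi]")
  if (length(s) > 1L) {
    z <- apply(psi, 2L, function(p) cumtrapz(s, sin(p)))
    if (min(z) < -tol)
      stop_domain("reconstructed centreline penetrates the surface (z < 0)")
  }
  invisible(beat)
}

# cumulative trapezoidal integral of y over x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

# trapezoidal weights for possibly non-uniform x
trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# interpolate psi(s, .) at an arbitrary phase, periodic in t with period 1
psi_at_phase <- function(beat, phase) {
  if (!is.numeric(phase) || length(phase) != 1L || !is.finite(phase) ||
      phase < 0 || phase >= 1)
    stop_domain("phase must be a single number in [0, 1)")
  t <- beat$t_grid
  if (length(t) == 1L) return(beat$psi[, 1L])
  # periodic extension: append first column at t[1] + 1
  tt <- c(t, t[1] + 1)
  pp <- cbind(beat$psi, beat$psi[, 1L])
  if (phase < tt[1]) phase <- phase + 1
  apply(pp, 1L, function(row) approx(tt, row, xout = phase)$y)
}

#' Reconstruct the cilium centreline at one phase of the beat
#'
#' Integrates the planar unit tangent \eqn{(\cos\psi, \sin\psi)} along
#' arclength by the cumulative trapezoidal rule. The base \eqn{s = 0} is at
#' the origin; the first coordinate is the reach along the beating direction
#' \eqn{\hat e}, the second the height \eqn{z} above the surface. The total
#' contour length is 1 by construction.
#'
#' @param beat a [beat_pattern()].
#' @param phase beat phase in `[0, 1)`; interpolated (periodically) if not a
#'   grid point.
#' @return A two-column matrix with columns `y` (along \eqn{\hat e}) and `z`,
#'   one row per `s_grid` sample.
#' @export
reconstruct_centerline <- function(beat, phase = 0) {
  validate_beat_pattern(beat)
  p <- psi_at_phase(beat, phase)
  s <- beat$s_grid
  cbind(y = cumtrapz(s, cos(p)), z = cumtrapz(s, sin(p)))
}

#' Mean-tangent tilt angle of a beat pattern
#'
#' Averages the unit tangent \eqn{(\cos\psi, \sin\psi)} uniformly over
#' arclength (trapezoidal weights on `s_grid`) and over the beat phase, and
#' returns the angle of the resulting mean vector measured from the beating
#' direction \eqn{\hat e}, in degrees. This is the tilt angle used to
#' coarse-grain a beating cilium into a static rod. Averaging the tangent
#' *angle* instead of the tangent *vector* is available via `method`.
#'
#' The result is invariant under phase shifts and time reversal of the beat.
#'
#' @param beat a [beat_pattern()].
#' @param method `"vector"` (default) averages the unit tangent vector;
#'   `"angle"` averages \eqn{\psi} itself.
#' @return Tilt angle in degrees.
#' @export
mean_tangent_angle <- function(beat, method = c("vector", "angle")) {
  method <- match.arg(method)
  validate_beat_pattern(beat)
  ws <- trapz_weights(beat$s_grid); ws <- ws / sum(ws)
  wt <- rep(1 / length(beat$t_grid), length(beat$t_grid))
  if (method == "angle") {
    return(rad2deg(sum(ws * (beat$psi %*% wt))))
  }
  mc <- sum(ws * (cos(beat$psi) %*% wt))
  ms <- sum(ws * (sin(beat$psi) %*% wt))
  rad2deg(atan2(ms, mc))
}

#' Stroke-extreme angles and top-view spanned area
#'
#' Summarises the coarse-grained geometry of a beat pattern. At every phase
#' the base-to-tip chord is computed from the reconstructed centreline.
#' `forward_angle` is the minimum chord elevation above the surface over the
#' phases whose tip lies forward of the base (along \eqn{+\hat e}) -- the
#' maximum tilt the cilium reaches at the power-stroke extreme -- and
#' `backward_angle` the same over the phases whose tip lies behind the base
#' (the recovery-stroke extreme), both in degrees. A side that the tip never
#' visits reports the elevation at its closest approach and contributes no
#' reach.
#'
#' The top-view spanned area is
#' `a_top = (forward reach + backward reach) * width`. The reaches are those
#' of the rigid-rod proxy swept between the two extreme elevations: a rod of
#' length \eqn{L} at elevation \eqn{\beta} reaches \eqn{L\cos\beta}
#' horizontally, and a side with no excursion past the base contributes 0.
#' `width` is the lateral footprint of the planar beat. The default
#' width is one cilium body width, \eqn{2r = 0.04 L}: a planar beat sweeps a
#' strip exactly one body width across. The minimum along-beat spacing at
#' which neighbouring beat envelopes do not overlap is
#' `d_par_min = forward reach + backward reach`.
#'
#' @param beat a [beat_pattern()].
#' @param width lateral footprint width in units of \eqn{L}; default `0.04`
#'   (one body width for a rod of radius 0.02).
#' @return A list of class `waveform_summary` with fields `alpha_tilt`,
#'   `forward_angle`, `backward_angle`, `reach_forward`, `reach_backward`,
#'   `d_par_min`, `a_top`, `width`.
#' @export
swept_summary <- function(beat, width = 0.04) {
  validate_beat_pattern(beat)
  stopifnot(is.numeric(width), length(width) == 1L, width >= 0)
  tips <- vapply(seq_along(beat$t_grid), function(j) {
    p <- beat$psi[, j]
    s <- beat$s_grid
    c(y = sum(trapz_weights(s) * cos(p)), z = sum(trapz_weights(s) * sin(p)))
  }, numeric(2))
  if (length(beat$s_grid) == 1L) {
    # degenerate: treat the single tangent as the chord
    tips <- rbind(y = cos(beat$psi[1, ]), z = sin(beat$psi[1, ]))
  }
  yt <- unname(tips["y", ]); zt <- unname(tips["z", ])
  elev <- ifelse(abs(yt) < 1e-12 & abs(zt) < 1e-12, 0,
                 rad2deg(atan2(zt, abs(yt))))
  fwd <- which(yt > 1e-12)
  bwd <- which(yt < -1e-12)
  forward_angle <- if (length(fwd)) min(elev[fwd]) else elev[which.max(yt)]
  backward_angle <- if (length(bwd)) min(elev[bwd]) else elev[which.min(yt)]
  # rigid-rod horizontal reach at the extreme elevations; zero when the tip
  # never passes the base on that side
  reach_f <- if (length(fwd)) cos(deg2rad(forward_angle)) else 0
  reach_b <- if (length(bwd)) cos(deg2rad(backward_angle)) else 0
  structure(list(
    alpha_tilt = mean_tangent_angle(beat),
    forward_angle = forward_angle,
    backward_angle = backward_angle,
    reach_forward = reach_f,
    reach_backward = reach_b,
    d_par_min = reach_f + reach_b,
    a_top = (reach_f + reach_b) * width,
    width = width
  ), class = "waveform_summary")
}

#' @export
print.waveform_summary <- function(x, ...) {
  cat("Beat-pattern summary\n")
  cat(sprintf("  mean-tangent tilt alpha: %.1f deg\n", x$alpha_tilt))
  cat(sprintf("  stroke-extreme elevations: %.1f / %.1f deg\n",
              x$forward_angle, x$backward_angle))
  cat(sprintf("  reach (fwd + back): %.3f + %.3f = d_par_min %.3f L\n",
              x$reach_forward, x$reach_backward, x$d_par_min))
  cat(sprintf("  top-view spanned area: %.4f L^2 (width %.3f L)\n",
              x$a_top, x$width))
  invisible(x)
}

#' @export
print.beat_pattern <- function(x, ...) {
  cat(sprintf("Beat pattern: %d arclength x %d phase samples\n",
              length(x$s_grid), length(x$t_grid)))
  invisible(x)
}

#' Read / write beat patterns
#'
#' Beat patterns serialise to long-format CSV with columns `s`, `t`,
#' `psi_rad`, or to JSON with fields `s_grid`, `t_grid`, `psi`
#' (column-major list of phase columns). Loaders validate the grids.
#'
#' @param beat a [beat_pattern()].
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_beat_pattern()` returns a [beat_pattern()];
#'   `write_beat_pattern()` returns `path` invisibly.
#' @export
write_beat_pattern <- function(beat, path) {
  validate_beat_pattern(beat)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # the psi matrix serialises as nested row arrays and reads back shaped
    jsonlite::write_json(
      list(s_grid = beat$s_grid, t_grid = beat$t_grid, psi = beat$psi),
      path, digits = NA, auto_unbox = FALSE)
  } else {
    df <- data.frame(
      s = rep(beat$s_grid, times = length(beat$t_grid)),
      t = rep(beat$t_grid, each = length(beat$s_grid)),
      psi_rad = as.vector(beat$psi))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_beat_pattern
#' @export
read_beat_pattern <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    psi <- if (is.matrix(x$psi)) x$psi else
      matrix(unlist(x$psi), length(x$s_grid))
    return(beat_pattern(x$s_grid, x$t_grid, psi))
  }
  df <- read.csv(path)
  s <- sort(unique(df$s)); t <- sort(unique(df$t))
  psi <- matrix(NA_real_, length(s), length(t))
  psi[cbind(match(df$s, s), match(df$t, t))] <- df$psi_rad
  if (anyNA(psi)) stop_domain("beat pattern CSV does not cover the full grid")
  beat_pattern(s, t, psi)
}
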