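# Ground-truth generators for every input the pipeline and fits consume:
# beating-cell bright-field movies, advected-tracer movies, alignment
# dose-response datasets, and parametric planar beat waveforms.

#' Sample from the von Mises circular distribution
#'
#' Best-Fisher rejection sampler. The direction-noise model for planted
#' beating directions: concentration `kappa = 0` is uniform on the circle,
#' large `kappa` concentrates on the mean direction. The expected alignment
#' of a von Mises sample with its mean direction has the closed form
#' \eqn{E[\cos(\theta - \mu)] = I_1(\kappa)/I_0(\kappa)}
#' (see [planted_alignment()]).
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, >= 0.
#' @return Angles in radians in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cq <- kappa * (r - f)
    if (cq * (2 - cq) - u[2] > 0 || log(cq / u[2]) + 1 - cq >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Expected alignment of a von Mises direction sample
#'
#' The mean resultant length \eqn{I_1(\kappa)/I_0(\kappa)}: the expected
#' value of the alignment parameter when beating directions are von Mises
#' distributed around the flow direction.
#'
#' @param kappa concentration parameter.
#' @return Expected alignment in `[0, 1)`.
#' @export
planted_alignment <- function(kappa) {
  ifelse(kappa == 0, 0, besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Specification of a synthetic ciliated field
#'
#' @param fov_px field-of-view side length, pixels (square frames).
#' @param pixel_size um per pixel.
#' @param n_cells number of ciliated cells to place.
#' @param r_range cell radius range, pixels.
#' @param cbf_mean,cbf_sd per-cell beat-frequency distribution, Hz.
#' @param direction_mean mean beating direction, radians (0 = +x).
#' @param kappa von Mises concentration of beating directions.
#' @param min_sep_factor minimum centre separation between cells as a
#'   multiple of the sum of their radii (1 = may touch; larger values space
#'   cells out so each interrogation box is dominated by a single cell).
#' @param noise_sd Gaussian read-noise standard deviation (intensity units).
#' @param amplitude oscillation amplitude of ciliated pixels.
#' @param baseline mean background intensity.
#' @param seed RNG seed (mandatory: generators are reproducible by contract).
#' @return A list of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(fov_px = 256, pixel_size = 0.2375,
                                 n_cells = 12, r_range = c(8, 14),
                                 cbf_mean = 22, cbf_sd = 3,
                                 direction_mean = 0, kappa = 4,
                                 min_sep_factor = 1, noise_sd = 5,
                                 amplitude = 20, baseline = 100, seed) {
  if (missing(seed)) stop_domain("a seed is mandatory for synthetic specs")
  stopifnot(fov_px >= 64, n_cells >= 1, length(r_range) == 2,
            r_range[1] <= r_range[2], cbf_mean > 0, kappa >= 0)
  structure(as.list(environment()), class = "synthetic_field_spec")
}

#' Plant a field of ciliated cells with known ground truth
#'
#' Places `n_cells` non-overlapping discs uniformly in the field (rejection
#' sampling with a retry cap), assigns each a beat frequency from
#' `N(cbf_mean, cbf_sd)` (truncated positive) and a beating direction drawn
#' von Mises around `direction_mean` with concentration `kappa`, so the
#' planted expected alignment is \eqn{I_1(\kappa)/I_0(\kappa)}.
#'
#' @param spec a [synthetic_field_spec()].
#' @param max_tries placement attempts per cell before giving up.
#' @return A list of class `field_layout`: `cells` (data frame `x`, `y`,
#'   `r`, `cbf_hz`, `dir_rad`), `label_map` (integer matrix), and `spec`.
#' @export
make_field <- function(spec, max_tries = 2000) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  set.seed(spec$seed)
  n <- spec$fov_px
  cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- runif(1, spec$r_range[1], spec$r_range[2])
      x <- runif(1, r + 1, n - r)
      y <- runif(1, r + 1, n - r)
      if (nrow(cells) == 0 ||
          all((cells$x - x)^2 + (cells$y - y)^2 >
                (spec$min_sep_factor * (cells$r + r))^2)) {
        cells <- rbind(cells, data.frame(x = x, y = y, r = r))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_domain(sprintf(
        "could not place cell %d of %d after %d tries; field too crowded",
        i, spec$n_cells, max_tries))
  }
  cbf <- abs(rnorm(spec$n_cells, spec$cbf_mean, spec$cbf_sd))
  dirs <- rvonmises(spec$n_cells, spec$direction_mean, spec$kappa)
  cells$cbf_hz <- cbf
  cells$dir_rad <- dirs
  lab <- matrix(0L, n, n)
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)   # column index = x
  yg <- matrix(seq_len(n), n, n)                 # row index = y
  for (i in seq_len(spec$n_cells)) {
    inside <- (xg - cells$x[i])^2 + (yg - cells$y[i])^2 <= cells$r[i]^2
    lab[inside] <- i
  }
  structure(list(cells = cells, label_map = lab, spec = spec),
            class = "field_layout")
}

#' Render a bright-field movie of beating cells
#'
#' Ciliated pixels oscillate as
#' \eqn{I(t) = I_0 + A \sin(2\pi f_c t + \phi_{px})} with the cell's planted
#' frequency and an independent random phase per pixel (cilia within a cell
#' are not synchronised in the image); Gaussian read noise is added
#' everywhere. Defaults mimic high-speed bright-field acquisition: 800
#' frames at 160 frames/s.
#'
#' @param layout a [make_field()] result.
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @return A [movie()].
#' @export
render_bf_movie <- function(layout, n_frames = 800, frame_rate = 160) {
  stopifnot(inherits(layout, "field_layout"))
  spec <- layout$spec
  set.seed(spec$seed + 1L)
  n <- spec$fov_px
  lab <- layout$label_map
  idx <- which(lab > 0L)
  fpx <- layout$cells$cbf_hz[lab[idx]]
  phase <- runif(length(idx), 0, 2 * pi)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  stack <- array(rnorm(n * n * n_frames, spec$baseline, spec$noise_sd),
                 dim = c(n, n, n_frames))
  # fill oscillating pixels frame by frame (vectorised over cell pixels)
  off <- (seq_len(n_frames) - 1L) * n * n
  for (k in seq_len(n_frames)) {
    stack[idx + off[k]] <- stack[idx + off[k]] +
      spec$amplitude * sin(2 * pi * fpx * tt[k] + phase)
  }
  movie(stack, frame_rate, spec$pixel_size)
}

#' Specification of a synthetic tracer movie
#'
#' @param n_particles tracer count; default gives on average 10 particles
#'   per 32-pixel interrogation box (standard PIV seeding practice).
#' @param particle_sigma_px rendered Gaussian spot sigma, pixels (a 1 um
#'   bead at 0.2375 um/px spans ~2 px).
#' @param speed_um_s flow-kernel peak speed per cell, um/s.
#' @param kernel_sigma_factor flow-kernel width as a multiple of the cell
#'   radius.
#' @param kernel_shape `"gaussian"` (long-tailed, like a Stokes source; the
#'   default) or `"compact"` (super-Gaussian, flat over the cell and fast
#'   decay).
#' @param n_frames,frame_rate acquisition (default 100 frames at 10 fps:
#'   10 s of tracer video).
#' @param resample_frac fraction of particles redrawn uniformly each frame,
#'   modelling tracer exchange with the focal plane (the planted 2-D flow is
#'   compressible, so without exchange tracers pile up at stagnation zones,
#'   which a real 3-D incompressible flow does not do).
#' @param brownian_sd_px per-frame Brownian jitter, pixels; the default 1.2
#'   px matches Stokes-Einstein diffusion of a 1 um bead in water at 37 C
#'   (~0.45 um^2/s) over a 0.1 s frame interval.
#' @param amplitude,noise_sd rendering intensity scale and read noise.
#' @return A list of class `synthetic_tracer_spec`.
#' @export
synthetic_tracer_spec <- function(n_particles = NULL, particle_sigma_px = 1.5,
                                  speed_um_s = 10, kernel_sigma_factor = 1.3,
                                  kernel_shape = c("gaussian", "compact"),
                                  n_frames = 100, frame_rate = 10,
                                  resample_frac = 0.08, brownian_sd_px = 1.2,
                                  amplitude = 200, noise_sd = 2) {
  kernel_shape <- match.arg(kernel_shape)
  structure(as.list(environment()), class = "synthetic_tracer_spec")
}

# planted velocity field (um/s) at pixel positions (x, y): sum of per-cell
# kernels oriented along each cell's direction. "gaussian" kernels have the
# slowly decaying tails of a Stokes flow source (every tracer moves);
# "compact" (super-Gaussian) kernels are flat over the cell and vanish fast,
# keeping neighbouring cells' directions independent in the rendered flow
planted_flow_at <- function(layout, tspec, x, y) {
  cells <- layout$cells
  sig <- tspec$kernel_sigma_factor * cells$r
  vx <- numeric(length(x)); vy <- numeric(length(x))
  for (i in seq_len(nrow(cells))) {
    d2 <- ((x - cells$x[i])^2 + (y - cells$y[i])^2) / sig[i]^2
    w <- if (tspec$kernel_shape == "compact") exp(-d2^2 / 2) else exp(-d2 / 2)
    vx <- vx + tspec$speed_um_s * cos(cells$dir_rad[i]) * w
    vy <- vy + tspec$speed_um_s * sin(cells$dir_rad[i]) * w
  }
  cbind(vx = vx, vy = vy)
}

#' Render a tracer movie advected by the planted flow
#'
#' Particles are advected by the superposition of per-cell Gaussian flow
#' kernels oriented along each cell's planted direction, plus Brownian
#' jitter, with periodic reinjection at the field boundaries, and rendered
#' as Gaussian spots over read noise. Advection is two-dimensional (a fixed
#' focal plane).
#'
#' @param layout a [make_field()] result.
#' @param tspec a [synthetic_tracer_spec()].
#' @return A [movie()] at the tracer frame rate.
#' @export
render_tracer_movie <- function(layout, tspec = synthetic_tracer_spec()) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(tspec, "synthetic_tracer_spec"))
  spec <- layout$spec
  set.seed(spec$seed + 2L)
  n <- spec$fov_px
  np <- tspec$n_particles %||% ceiling(10 * (n / 32)^2)
  px <- runif(np, 1, n)
  py <- runif(np, 1, n)
  dt <- 1 / tspec$frame_rate
  sig <- tspec$particle_sigma_px
  halo <- ceiling(3 * sig)
  stack <- array(rnorm(n * n * tspec$n_frames, 0, tspec$noise_sd),
                 dim = c(n, n, tspec$n_frames))
  for (k in seq_len(tspec$n_frames)) {
    # render current positions as Gaussian spots
    frame <- matrix(0, n, n)
    for (p in seq_len(np)) {
      cx <- px[p]; cy <- py[p]
      c0 <- max(1L, floor(cx) - halo); c1 <- min(n, ceiling(cx) + halo)
      r0 <- max(1L, floor(cy) - halo); r1 <- min(n, ceiling(cy) + halo)
      if (c0 > c1 || r0 > r1) next
      xs <- c0:c1; ys <- r0:r1
      gx <- exp(-(xs - cx)^2 / (2 * sig^2))
      gy <- exp(-(ys - cy)^2 / (2 * sig^2))
      frame[ys, xs] <- frame[ys, xs] + tspec$amplitude * outer(gy, gx)
    }
    stack[, , k] <- stack[, , k] + frame
    # advect to next frame
    v <- planted_flow_at(layout, tspec, px, py)    # um/s
    px <- px + v[, "vx"] / spec$pixel_size * dt +
      rnorm(np, 0, tspec$brownian_sd_px)
    py <- py + v[, "vy"] / spec$pixel_size * dt +
      rnorm(np, 0, tspec$brownian_sd_px)
    px <- ((px - 1) %% n) + 1
    py <- ((py - 1) %% n) + 1
    # tracer exchange with the focal plane
    if (tspec$resample_frac > 0) {
      ridx <- which(runif(np) < tspec$resample_frac)
      px[ridx] <- runif(length(ridx), 1, n)
      py[ridx] <- runif(length(ridx), 1, n)
    }
  }
  movie(stack, tspec$frame_rate, spec$pixel_size)
}

#' Synthetic alignment dose-response dataset
#'
#' Generates per-FOV alignment values
#' \eqn{\Phi = 1 - \exp(-\tau/\tau_c) + N(0, sd)}, clipped to `[-1, 1]`,
#' over a grid of applied shear stresses.
#'
#' @param tau_grid shear stresses, dyne/cm^2, all positive.
#' @param tau_c planted critical shear stress.
#' @param noise_sd Gaussian noise standard deviation on \eqn{\Phi}.
#' @param n_per_tau replicate FOVs per stress.
#' @param seed RNG seed.
#' @return A data frame with columns `tau`, `phi`, `fov`.
#' @export
make_dose_dataset <- function(tau_grid, tau_c, noise_sd = 0.05,
                              n_per_tau = 1, seed = 1) {
  stopifnot(all(tau_grid > 0), tau_c > 0, noise_sd >= 0, n_per_tau >= 1)
  set.seed(seed)
  tau <- rep(tau_grid, each = n_per_tau)
  phi <- 1 - exp(-tau / tau_c) + rnorm(length(tau), 0, noise_sd)
  data.frame(tau = tau, phi = pmin(pmax(phi, -1), 1),
             fov = rep(seq_len(n_per_tau), times = length(tau_grid)))
}

#' Parametric planar beat pattern
#'
#' A travelling-bend family with tunable power/recovery asymmetry:
#' \deqn{\psi(s, t) = \psi_0 - s\,[a + b \sin(2\pi t - \lambda s)]}
#' with rest orientation \eqn{\psi_0} (default vertical), mean bend `a`
#' (`asymmetry`), sweep amplitude `b` (`amplitude`) and wave lag `lambda`.
#' With `asymmetry = 0` the stroke is symmetric about the rest orientation
#' and the mean tangent keeps the rest tilt; `asymmetry != 0` biases the
#' pattern towards the power stroke. [calibrate_beat_extremes()] returns the
#' (`amplitude`, `asymmetry`) pair whose base-to-tip chord extremes hit
#' prescribed elevations.
#'
#' @param amplitude sweep amplitude `b`, radians.
#' @param asymmetry mean bend `a`, radians.
#' @param base_angle rest tangent angle \eqn{\psi_0}, radians.
#' @param wave_lag travelling-wave phase lag \eqn{\lambda}, radians
#'   (0 = rigid rocking).
#' @param n_s,n_t grid sizes.
#' @return A [beat_pattern()].
#' @export
make_beat_pattern <- function(amplitude = 0.5, asymmetry = 0,
                              base_angle = pi / 2, wave_lag = 0,
                              n_s = 25, n_t = 24) {
  stopifnot(n_s >= 2, n_t >= 1)
  s <- seq(0, 1, length.out = n_s)
  t <- seq(0, 1 - 1 / n_t, length.out = n_t)
  psi <- outer(s, t, function(ss, tt)
    base_angle - ss * (asymmetry + amplitude * sin(2 * pi * tt - wave_lag * ss)))
  psi <- ((psi + pi) %% (2 * pi)) - pi       # wrap into (-pi, pi]
  psi[psi == -pi] <- pi
  beat_pattern(s, t, psi)
}

#' @rdname make_beat_pattern
#' @param forward_deg,backward_deg target chord elevations (degrees) at the
#'   power- and recovery-stroke extremes.
#' @param n_s_cal,n_t_cal grid used during calibration.
#' @details The chord elevation at the stroke extreme is measured at the
#'   phase of maximal reach, which for a bent centreline is not the phase of
#'   maximal bend, so the calibration is a parameter search: starting from
#'   the straight-chord guess (a uniform bend \eqn{\gamma} has chord
#'   elevation \eqn{90^\circ - \gamma/2}), `(amplitude, asymmetry)` are
#'   refined by Nelder-Mead until [swept_summary()] reproduces the target
#'   angles.
#' @export
calibrate_beat_extremes <- function(forward_deg = 23, backward_deg = 18,
                                    n_s_cal = 101, n_t_cal = 64) {
  gf <- deg2rad(2 * (90 - forward_deg))
  gb <- deg2rad(2 * (90 - backward_deg))
  obj <- function(p) {
    sm <- tryCatch(
      swept_summary(make_beat_pattern(p[1], p[2], n_s = n_s_cal, n_t = n_t_cal)),
      error = function(e) NULL)
    if (is.null(sm)) return(1e6)
    (sm$forward_angle - forward_deg)^2 + (sm$backward_angle - backward_deg)^2
  }
  fit <- stats::optim(c((gf + gb) / 2, (gf - gb) / 2), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  list(amplitude = fit$par[1], asymmetry = fit$par[2],
       residual_deg = sqrt(fit$value))
}
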