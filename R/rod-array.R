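#' Configuration of a tilted-rod lattice
#'
#' Describes the regular array of static rigid rods used to coarse-grain a
#' cilia carpet. Every rod has unit length \eqn{L = 1} and radius
#' \eqn{r = 0.02}, is elevated by `tilt_alpha` degrees from the surface plane
#' towards the beating direction \eqn{\hat e}, and its base sits `wall_gap`
#' above the no-slip wall. The lattice has `n_cols` rods along \eqn{\hat e}
#' spaced `d_par` apart and `n_rows` rods perpendicular to \eqn{\hat e}
#' spaced `d_perp` apart. `theta` is the angle (radians) between \eqn{\hat e}
#' and the imposed flow direction \eqn{\hat y}.
#'
#' Spacings are validated against the non-overlap minima: `d_perp` must be at
#' least two body widths (`4 * radius = 0.08` by default) and `d_par` at
#' least `d_par_min`, the along-beat extent of the beat envelope (default
#' `cos(23 deg) + cos(18 deg)` from the stroke-extreme chord angles).
#'
#' @param n_rows,n_cols lattice counts; the array has `n_rows * n_cols` rods.
#' @param d_perp centre spacing perpendicular to the beating direction
#'   (units of \eqn{L}).
#' @param d_par centre spacing along the beating direction (units of
#'   \eqn{L}); default `d_par_min`.
#' @param tilt_alpha rod elevation from the surface plane, degrees.
#' @param rod_length rod length \eqn{L} (the non-dimensionalisation unit).
#' @param radius rod radius in units of \eqn{L}.
#' @param wall_gap base height above the wall in units of \eqn{L}.
#' @param theta angle between beating direction and flow, radians, in
#'   `[0, pi/2]` (negative values allowed for symmetry checks).
#' @param d_par_min,d_perp_min overridable spacing minima.
#' @return An object of class `rod_array_config`.
#' @export
rod_array_config <- function(n_rows = 9, n_cols = 9,
                             d_perp = 0.08, d_par = NULL,
                             tilt_alpha = 53, rod_length = 1, radius = 0.02,
                             wall_gap = 0.05, theta = pi / 2,
                             d_par_min = cos(deg2rad(23)) + cos(deg2rad(18)),
                             d_perp_min = 4 * radius) {
  d_par <- d_par %||% d_par_min
  stopifnot(n_rows >= 1, n_cols >= 1, rod_length > 0, radius > 0,
            wall_gap >= 0, abs(theta) <= pi / 2)
  if (n_rows > 1 && d_perp < d_perp_min - 1e-12)
    stop_domain(sprintf(
      "d_perp = %.3f violates the minimum perpendicular spacing %.3f (two body widths)",
      d_perp, d_perp_min))
  if (n_cols > 1 && d_par < d_par_min - 1e-12)
    stop_domain(sprintf(
      "d_par = %.3f violates the minimum along-beat spacing %.3f (beat envelopes overlap)",
      d_par, d_par_min))
  structure(list(n_rows = n_rows, n_cols = n_cols, d_perp = d_perp,
                 d_par = d_par, tilt_alpha = tilt_alpha,
                 rod_length = rod_length, radius = radius,
                 wall_gap = wall_gap, theta = theta,
                 d_par_min = d_par_min, d_perp_min = d_perp_min),
            class = "rod_array_config")
}

#' Discretization and flow parameters for the Stokes solve
#'
#' @param segments_per_rod number of centreline quadrature nodes per rod
#'   (\eqn{M \ge 8}).
#' @param regularization slenderness parameter \eqn{\epsilon} entering the
#'   local slender-body operator through \eqn{c = -\ln(\epsilon^2 e)};
#'   defaults to the rod aspect ratio \eqn{r/L}.
#' @param shear_rate imposed shear rate \eqn{\dot\gamma} (non-dimensional).
#' @param viscosity fluid viscosity \eqn{\eta} (non-dimensional).
#' @return An object of class `stokes_discretization`.
#' @export
stokes_discretization <- function(segments_per_rod = 24, regularization = 0.02,
                                  shear_rate = 1, viscosity = 1) {
  stopifnot(segments_per_rod >= 8, regularization > 0, viscosity > 0)
  structure(list(segments_per_rod = as.integer(segments_per_rod),
                 regularization = regularization,
                 shear_rate = shear_rate, viscosity = viscosity),
            class = "stokes_discretization")
}

#' Place rods of an array in space
#'
#' Builds the rectangular lattice, centred on the origin, with the
#' perpendicular lattice direction spaced `d_perp` and the along-beat
#' direction spaced `d_par`. Every rod points along
#' \eqn{\cos\alpha\,\hat e + \sin\alpha\,\hat z}, where the beating
#' direction \eqn{\hat e = (\sin\theta, \cos\theta, 0)} makes angle `theta`
#' with the flow direction \eqn{\hat y}; bases sit at `z = wall_gap`.
#'
#' @param config a [rod_array_config()].
#' @param disc a [stokes_discretization()]; sets the centreline nodes
#'   (segment midpoints).
#' @return A list of class `rod_geometry` with the base points (`bases`,
#'   rods x 3), the shared unit axis (`axis`), node positions (`nodes`,
#'   (rods*M) x 3), per-node rod index (`rod`), node arclengths (`s`),
#'   quadrature weight (`h`), and the originating `config` and `disc`.
#' @export
place_rods <- function(config, disc = stokes_discretization()) {
  stopifnot(inherits(config, "rod_array_config"),
            inherits(disc, "stokes_discretization"))
  alpha <- deg2rad(config$tilt_alpha)
  theta <- config$theta
  ehat <- c(sin(theta), cos(theta), 0)
  perp <- c(cos(theta), -sin(theta), 0)
  ax <- c(cos(alpha) * ehat[1:2], sin(alpha))
  ir <- seq_len(config$n_rows) - (config$n_rows + 1) / 2
  ic <- seq_len(config$n_cols) - (config$n_cols + 1) / 2
  grid <- expand.grid(row = ir, col = ic)
  L <- config$rod_length
  bases <- cbind(
    grid$row * config$d_perp * perp[1] + grid$col * config$d_par * ehat[1],
    grid$row * config$d_perp * perp[2] + grid$col * config$d_par * ehat[2],
    config$wall_gap)
  M <- disc$segments_per_rod
  h <- L / M
  s <- (seq_len(M) - 0.5) * h
  n_rods <- nrow(bases)
  rod <- rep(seq_len(n_rods), each = M)
  sv <- rep(s, n_rods)
  nodes <- cbind(bases[rod, 1] + sv * ax[1],
                 bases[rod, 2] + sv * ax[2],
                 bases[rod, 3] + sv * ax[3])
  structure(list(bases = bases, axis = ax, ehat = ehat, nodes = nodes,
                 rod = rod, s = sv, h = h, n_rods = n_rods,
                 config = config, disc = disc),
            class = "rod_geometry")
}

#' Imposed ambient shear flow
#'
#' The external flow is a simple shear along \eqn{\hat y} above a no-slip
#' wall at \eqn{z = 0}: \eqn{u_\infty(x) = (0, \dot\gamma z, 0)}.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix of positions;
#'   all must have \eqn{z \ge 0}.
#' @param shear_rate shear rate \eqn{\dot\gamma}.
#' @return A matrix of the same shape as `points` with the flow velocity.
#' @export
ambient_shear <- function(points, shear_rate = 1) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  if (ncol(p) != 3) stop_domain("points must have 3 columns")
  if (any(p[, 3] < 0)) stop_domain("ambient shear is defined for z >= 0 only")
  u <- cbind(0, shear_rate * p[, 3], 0)
  if (is.null(dim(points))) u[1, ] else u
}
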