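#' Torsional spring at the cilium base
#'
#' The resistance of the anchoring (phenomenologically, the apical actin
#' mesh) to a rotation of the beating direction is modelled as a linear
#' torsional spring. With the beating direction initially perpendicular to
#' the imposed flow (rest angle \eqn{\pi/2}), the restoring torque at angle
#' \eqn{\theta} is \eqn{T_{el} = k (\pi/2 - \theta)}: zero at rest, maximal
#' at full alignment \eqn{\theta = 0}.
#'
#' @param stiffness non-negative spring stiffness \eqn{k}, in the same
#'   non-dimensional torque units as [rod_torque_z()]
#'   (\eqn{\eta \dot\gamma L^3} per radian).
#' @param rest_angle rest angle, radians (default \eqn{\pi/2}).
#' @return An object of class `spring_model`.
#' @export
spring_model <- function(stiffness, rest_angle = pi / 2) {
  stopifnot(is.numeric(stiffness), length(stiffness) == 1L, stiffness >= 0)
  structure(list(stiffness = stiffness, rest_angle = rest_angle),
            class = "spring_model")
}

#' Elastic restoring torque
#'
#' @param theta beating angle(s), radians, in `[0, rest_angle]`.
#' @param spring a [spring_model()].
#' @return Torque \eqn{k (\pi/2 - \theta)} (vectorised over `theta`).
#' @export
elastic_torque <- function(theta, spring) {
  stopifnot(inherits(spring, "spring_model"))
  if (any(theta < -1e-12 | theta > spring$rest_angle + 1e-12))
    stop_domain("theta outside [0, rest angle]")
  spring$stiffness * (spring$rest_angle - theta)
}

#' Equilibrium beating angle from torque balance
#'
#' The beating direction settles where the hydrodynamic torque pulling it
#' towards the flow equals the elastic torque pulling it back to its rest
#' orientation: the root of
#' \eqn{g(\theta) = T_{hydro}(\theta) - k(\pi/2 - \theta)}. The sampled
#' hydrodynamic curve is interpolated with a monotone piecewise-cubic spline
#' (Hyman filtering, no overshoot) and the root bracketed and refined by
#' bisection. Special cases: `k = 0` gives full alignment
#' (\eqn{\theta^* = 0}); if no crossing exists below the rest angle the
#' boundary solution \eqn{\theta^* = \pi/2} is returned flagged as not
#' converged. If the curve crosses more than once the smallest root is
#' returned with a warning.
#'
#' @param theta_grid angles (radians) at which the hydrodynamic torque was
#'   sampled; must cover `[0, pi/2]` with `T(0) = 0` and non-negative values.
#' @param torque hydrodynamic torques at `theta_grid` (units
#'   \eqn{\eta\dot\gamma L^3}).
#' @param spring a [spring_model()].
#' @param tol bisection tolerance on \eqn{\theta^*}, radians.
#' @return A list of class `equilibrium_result`: `theta_star`, `phi`
#'   (\eqn{\cos\theta^*}), `converged`, `residual` (torque imbalance at the
#'   root), `n_crossings`.
#' @export
equilibrium_angle <- function(theta_grid, torque, spring, tol = 1e-10) {
  stopifnot(inherits(spring, "spring_model"))
  o <- order(theta_grid)
  theta_grid <- theta_grid[o]; torque <- torque[o]
  if (length(theta_grid) < 2L)
    stop_domain("need at least two sampled angles")
  if (abs(torque[1]) > 1e-6 * max(abs(torque), 1e-12) && theta_grid[1] == 0)
    warning("hydrodynamic torque at theta = 0 is not ~0")
  if (any(torque < -1e-9))
    stop_domain("hydrodynamic torque curve must be non-negative on [0, pi/2]")
  k <- spring$stiffness
  rest <- spring$rest_angle
  if (k == 0) {
    return(structure(list(theta_star = 0, phi = 1, converged = TRUE,
                          residual = torque[1], n_crossings = 1L),
                     class = "equilibrium_result"))
  }
  Tfun <- if (length(unique(torque)) == 1L)
    function(x) rep(torque[1], length(x))
  else
    # hyman needs globally monotone samples; fall back to Fritsch-Carlson
    # (still overshoot-free) if solver noise breaks monotonicity
    tryCatch(splinefun(theta_grid, torque, method = "hyman"),
             error = function(e)
               splinefun(theta_grid, torque, method = "monoH.FC"))
  g <- function(x) Tfun(x) - k * (rest - x)
  # scan for sign changes
  xs <- seq(theta_grid[1], min(max(theta_grid), rest), length.out = 512L)
  gs <- g(xs)
  sgn <- sign(gs)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0 | gs[-length(gs)] == 0)
  if (length(cross) == 0L) {
    if (gs[length(gs)] <= 0) {
      # elastic torque dominates everywhere: boundary solution at rest angle
      return(structure(list(theta_star = rest, phi = cos(rest),
                            converged = FALSE,
                            residual = g(rest), n_crossings = 0L),
                       class = "equilibrium_result"))
    }
    # hydrodynamic torque dominates everywhere sampled: root at lower edge
    root <- theta_grid[1]
  } else {
    if (length(cross) > 1L)
      warning(sprintf(
        "torque balance has %d crossings; returning the smallest root (curve may be non-monotone)",
        length(cross)))
    lo <- xs[cross[1]]; hi <- xs[cross[1] + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g(lo)) && g(mid) != 0) lo <- mid else hi <- mid
    }
    root <- (lo + hi) / 2
  }
  structure(list(theta_star = root, phi = cos(root), converged = TRUE,
                 residual = g(root), n_crossings = max(1L, length(cross))),
            class = "equilibrium_result")
}

#' Alignment surface over cilia density and spring stiffness
#'
#' Applies [equilibrium_angle()] to every (density, stiffness) pair: the
#' hydrodynamic torque curve \eqn{T(\theta)} at each density is taken from a
#' [screening_sweep()] table (un-normalised, i.e. multiplied back by the
#' isolated reference), balanced against the spring, and reduced to the
#' alignment parameter \eqn{\Phi = \cos\theta^*}. \eqn{\Phi} is 1 for
#' unresisted cilia (`k = 0`) and decreases both with stiffness and with
#' density (denser carpets are hydrodynamically screened and feel less
#' torque).
#'
#' @param screening a `screening_table` from [screening_sweep()]; its
#'   `theta_grid` must start at 0 and reach \eqn{\pi/2}.
#' @param k_grid non-negative spring stiffnesses.
#' @return A list of class `phi_surface`: `rho_grid`, `k_grid`, matrices
#'   `phi` and `theta_star` (k x rho), `converged`.
#' @export
phi_surface <- function(screening, k_grid) {
  stopifnot(inherits(screening, "screening_table"), all(k_grid >= 0))
  if (!is.finite(screening$isolated_reference))
    stop_domain("screening table lacks the isolated reference torque")
  th <- screening$theta_grid
  phi <- matrix(NA_real_, length(k_grid), length(screening$rho_grid))
  tst <- phi; conv <- matrix(NA, length(k_grid), length(screening$rho_grid))
  for (ir in seq_along(screening$rho_grid)) {
    curve <- screening$normalized_torque[, ir] * screening$isolated_reference
    curve <- pmax(curve, 0)           # clip solver noise at theta = 0
    for (ik in seq_along(k_grid)) {
      eq <- equilibrium_angle(th, curve, spring_model(k_grid[ik]))
      phi[ik, ir] <- eq$phi
      tst[ik, ir] <- eq$theta_star
      conv[ik, ir] <- eq$converged
    }
  }
  structure(list(rho_grid = screening$rho_grid, k_grid = k_grid,
                 phi = phi, theta_star = tst, converged = conv),
            class = "phi_surface")
}

#' @export
print.phi_surface <- function(x, ...) {
  cat(sprintf("Alignment surface: %d stiffness x %d density values\n",
              length(x$k_grid), length(x$rho_grid)))
  m <- round(x$phi, 3)
  dimnames(m) <- list(k = sprintf("%.3g", x$k_grid),
                      rho = sprintf("%.3f", x$rho_grid))
  print(m)
  invisible(x)
}
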