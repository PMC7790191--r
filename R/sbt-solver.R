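# Slender-body-theory Stokes solver for static rod arrays above a no-slip
# wall. Each rod is represented by a line of point-force densities at its
# centreline nodes. The velocity induced at node i by the force density g is
#
#   8*pi*eta * u_i = Lambda g_i + sum_{j != i} h [ S(x_i - x_j) g_j
#                       - same-rod local subtraction ] + sum_j h B(x_i, y_j) g_j
#
# with Lambda = c (I + tt') + 2 (I - tt'), c = -ln(eps^2 e), S the free-space
# Stokeslet (Oseen tensor) and B the Blake image system that cancels S on the
# wall z = 0. Setting the total velocity (ambient shear + induced) to zero at
# every node and solving the dense linear system yields g, the force per unit
# length the rods exert on the fluid; the hydrodynamic force density on the
# rods is -g.

# Blake (1971) image system: velocity tensor at x due to the image of a unit
# point force at y = (y1, y2, hs) above the wall z = 0. Vectorised over all
# target/source pairs: inputs are N x N matrices. Returns the (i, j)
# component (target velocity component i, force component j).
blake_image_component <- function(i, j, R1, R2, R3, HS, q1, q3, q5) {
  Rl <- list(R1, R2, R3)
  Dj <- if (j == 3) -1 else 1
  dij <- as.numeric(i == j); di3 <- as.numeric(i == 3); d3j <- as.numeric(j == 3)
  S <- Rl[[i]] * Rl[[j]] / q3
  if (i == j) S <- S + 1 / q1
  deriv <- HS * (dij / q3 - 3 * Rl[[i]] * Rl[[j]] / q5) +
    di3 * Rl[[j]] / q3 - (dij * R3 + d3j * Rl[[i]]) / q3 +
    3 * Rl[[i]] * R3 * Rl[[j]] / q5
  -S + 2 * HS * Dj * deriv
}

# Dense 3N x 3N mobility-like matrix (in units of 1/(8*pi*eta)); unknowns are
# ordered component-major: (g_x at all nodes, g_y, g_z).
build_sbt_matrix <- function(geometry, wall = TRUE) {
  disc <- geometry$disc
  X <- geometry$nodes
  N <- nrow(X)
  h <- geometry$h
  ax <- geometry$axis
  eps <- disc$regularization / geometry$config$rod_length
  cc <- -log(eps^2 * exp(1))
  tt <- outer(ax, ax)
  I3 <- diag(3)
  Lam <- cc * (I3 + tt) + 2 * (I3 - tt)

  D1 <- outer(X[, 1], X[, 1], "-")
  D2 <- outer(X[, 2], X[, 2], "-")
  D3 <- outer(X[, 3], X[, 3], "-")
  r2 <- D1 * D1 + D2 * D2 + D3 * D3
  diag(r2) <- 1                        # placeholder; diagonal handled by Lam
  if (N > 1 && min(r2[upper.tri(r2)]) < (2 * disc$regularization)^2 * 1e-6)
    stop_domain("overlapping rods: nodes nearly coincide, system is singular")
  r1 <- sqrt(r2); r3 <- r2 * r1
  Dl <- list(D1, D2, D3)
  off <- !diag(N)

  # same-rod local subtraction: sum over j on the same rod of 1/|s_i - s_j|
  same <- outer(geometry$rod, geometry$rod, "==")
  dsinv <- outer(geometry$s, geometry$s,
                 function(a, b) 1 / pmax(abs(a - b), .Machine$double.eps))
  dsinv[!same | diag(N) > 0] <- 0
  diag(dsinv) <- 0
  rowsub <- rowSums(dsinv)

  if (wall) {
    HS <- matrix(X[, 3], N, N, byrow = TRUE)
    R1 <- D1; R2 <- D2; R3 <- outer(X[, 3], X[, 3], "+")
    q2 <- R1 * R1 + R2 * R2 + R3 * R3
    q1 <- sqrt(q2); q3 <- q2 * q1; q5 <- q3 * q2
  }

  A <- matrix(0, 3 * N, 3 * N)
  idxN <- seq_len(N)
  for (i in 1:3) for (j in 1:3) {
    S <- Dl[[i]] * Dl[[j]] / r3
    if (i == j) S <- S + 1 / r1
    S[!off] <- 0
    blk <- h * S
    if (wall)
      blk <- blk + h * blake_image_component(i, j, R1, R2, R3, HS, q1, q3, q5)
    # diagonal: local operator minus the same-rod subtraction
    dd <- Lam[i, j] - h * (I3[i, j] + tt[i, j]) * rowsub
    blk[cbind(idxN, idxN)] <- blk[cbind(idxN, idxN)] + dd
    A[(i - 1) * N + idxN, (j - 1) * N + idxN] <- blk
  }
  A
}

#' Solve for slender-body force densities on a static rod array
#'
#' Solves the slender-body integral relation (local drag operator, non-local
#' Stokeslet interactions along and between rods, and Blake-type wall images)
#' so that the total fluid velocity vanishes on every centreline node of the
#' static rods held in the ambient shear flow. The returned force density is
#' the hydrodynamic force per unit length exerted by the fluid on the rods.
#'
#' @param geometry a [place_rods()] result.
#' @param disc optional [stokes_discretization()] overriding the one stored
#'   in `geometry` (the geometry is then re-discretised).
#' @param wall logical; include the no-slip wall image system (default
#'   `TRUE`). Disabling it yields the free-space slender-body solution.
#' @param uinf optional ambient velocity at the centreline nodes
#'   ((rods*M) x 3 matrix) replacing the default shear profile, e.g. a
#'   uniform stream for drag benchmarks.
#' @return A list of class `sbt_solution`: `force_density` ((rods*M) x 3
#'   matrix, force per unit length on the rods), `geometry`, `wall`, and the
#'   max residual velocity `residual` of the linear solve.
#' @export
solve_force_density <- function(geometry, disc = NULL, wall = TRUE,
                                uinf = NULL) {
  stopifnot(inherits(geometry, "rod_geometry"))
  if (!is.null(disc)) geometry <- place_rods(geometry$config, disc)
  d <- geometry$disc
  A <- build_sbt_matrix(geometry, wall = wall) / (8 * pi * d$viscosity)
  uinf <- uinf %||% ambient_shear(geometry$nodes, d$shear_rate)
  stopifnot(nrow(uinf) == nrow(geometry$nodes), ncol(uinf) == 3)
  rhs <- -as.vector(uinf)              # component-major: (x, y, z) blocks
  g <- tryCatch(solve(A, rhs), error = function(e)
    stop_domain("slender-body system is singular or ill-conditioned: ",
                conditionMessage(e)))
  res <- max(abs(A %*% g - rhs))
  if (res > 1e-8 * max(1, max(abs(rhs))))
    warning(sprintf("slender-body solve residual %.2e", res))
  N <- nrow(geometry$nodes)
  gmat <- cbind(g[seq_len(N)], g[N + seq_len(N)], g[2 * N + seq_len(N)])
  structure(list(force_density = -gmat, geometry = geometry, wall = wall,
                 residual = res),
            class = "sbt_solution")
}

# disturbance velocity induced at arbitrary points by a solved force density
# (used to verify the no-slip condition on the wall)
induced_velocity <- function(solution, points) {
  geom <- solution$geometry
  d <- geom$disc
  X <- geom$nodes
  g <- -solution$force_density          # force on fluid
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  h <- geom$h
  np <- nrow(P)
  D1 <- outer(P[, 1], X[, 1], "-")
  D2 <- outer(P[, 2], X[, 2], "-")
  D3 <- outer(P[, 3], X[, 3], "-")
  r2 <- D1 * D1 + D2 * D2 + D3 * D3
  r1 <- sqrt(r2); r3 <- r2 * r1
  Dl <- list(D1, D2, D3)
  u <- matrix(0, np, 3)
  HS <- matrix(X[, 3], np, ncol(D1), byrow = TRUE)
  R1 <- D1; R2 <- D2; R3 <- outer(P[, 3], X[, 3], "+")
  q2 <- R1 * R1 + R2 * R2 + R3 * R3
  q1 <- sqrt(q2); q3 <- q2 * q1; q5 <- q3 * q2
  for (i in 1:3) for (j in 1:3) {
    S <- Dl[[i]] * Dl[[j]] / r3
    if (i == j) S <- S + 1 / r1
    B <- if (solution$wall)
      blake_image_component(i, j, R1, R2, R3, HS, q1, q3, q5) else 0
    u[, i] <- u[, i] + (h / (8 * pi * d$viscosity)) * ((S + B) %*% g[, j])
  }
  u
}

#' Hydrodynamic z-torque on each rod
#'
#' Integrates \eqn{(x - x_{base}) \times f} over each rod (quadrature over
#' centreline nodes) and returns the component about the vertical axis
#' through the rod base -- the degree of freedom along which the beating
#' direction can realign. Torques are non-dimensionalised by
#' \eqn{\eta \dot\gamma L^3}.
#'
#' @param solution a [solve_force_density()] result.
#' @return A list of class `torque_result`: `per_rod_torque_z`,
#'   `mean_torque`, and the non-dimensionalisation factor `scale`
#'   (\eqn{\eta \dot\gamma L^3}).
#' @export
rod_torque_z <- function(solution) {
  stopifnot(inherits(solution, "sbt_solution"))
  geom <- solution$geometry
  d <- geom$disc
  f <- solution$force_density
  rel1 <- geom$nodes[, 1] - geom$bases[geom$rod, 1]
  rel2 <- geom$nodes[, 2] - geom$bases[geom$rod, 2]
  tz <- geom$h * (rel1 * f[, 2] - rel2 * f[, 1])
  scale <- d$viscosity * d$shear_rate * geom$config$rod_length^3
  per_rod <- as.numeric(tapply(tz, geom$rod, sum)) / scale
  structure(list(per_rod_torque_z = per_rod, mean_torque = mean(per_rod),
                 scale = scale),
            class = "torque_result")
}

#' Torque on a single isolated rod
#'
#' Convenience wrapper: one rod at the origin, solved and reduced to its
#' non-dimensional z-torque. With the default geometry (tilt 53 deg, radius
#' 0.02, wall gap 0.05) and flow perpendicular to the beating plane
#' (`theta = pi/2`) this is the reference torque \eqn{T_0} used to normalise
#' screening tables.
#'
#' @param theta angle between beating direction and flow, radians.
#' @param disc a [stokes_discretization()].
#' @param config optional single-rod [rod_array_config()]; `theta` overrides
#'   its angle.
#' @param wall include the wall image system.
#' @return Non-dimensional z-torque (scalar).
#' @export
isolated_rod_torque <- function(theta = pi / 2, disc = stokes_discretization(),
                                config = NULL, wall = TRUE) {
  cfg <- config %||% rod_array_config(n_rows = 1, n_cols = 1)
  cfg$n_rows <- 1L; cfg$n_cols <- 1L
  cfg$theta <- theta
  sol <- solve_force_density(place_rods(cfg, disc), wall = wall)
  rod_torque_z(sol)$mean_torque
}

#' Hydrodynamic screening sweep over cilia density and flow angle
#'
#' For each perpendicular spacing `d_perp` and each angle `theta`, solves the
#' rod-array Stokes problem, averages the z-torque over all rods, and
#' normalises by the isolated-rod reference \eqn{T_0(\theta = \pi/2)}
#' computed with the same discretization. The ciliated area fraction is
#' \eqn{\rho = A_{top} / (d_{par} d_{perp})}, with the per-cilium top-view
#' footprint `a_top` defaulting to `d_par_min * 0.04` (beat envelope length
#' times one body width, see [swept_summary()]).
#'
#' @param d_perp_list perpendicular spacings to sweep (units of \eqn{L});
#'   default the standard set `0.08, 0.16, 0.24, 0.32, 0.40`.
#' @param theta_grid flow angles (radians) to sweep.
#' @param config template [rod_array_config()] supplying lattice size, tilt
#'   and `d_par`.
#' @param disc a [stokes_discretization()].
#' @param a_top per-cilium top-view spanned area (units \eqn{L^2}).
#' @param progress logical; print one line per solve.
#' @return A list of class `screening_table`: `theta_grid`, `rho_grid`,
#'   `d_perp_list`, matrix `normalized_torque` (theta x rho, normalised by
#'   `isolated_reference`), `torque` (unnormalised), `isolated_reference`,
#'   and metadata (`n_rods`, `segments_per_rod`, `d_par`, `a_top`).
#' @export
screening_sweep <- function(d_perp_list = c(0.08, 0.16, 0.24, 0.32, 0.40),
                            theta_grid = c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2),
                            config = rod_array_config(),
                            disc = stokes_discretization(),
                            a_top = NULL, progress = FALSE) {
  stopifnot(length(d_perp_list) >= 1, length(theta_grid) >= 1)
  a_top <- a_top %||% (config$d_par_min * 0.04)
  t0 <- isolated_rod_torque(pi / 2, disc, config)
  rho <- a_top / (config$d_par * d_perp_list)
  torque <- matrix(NA_real_, length(theta_grid), length(d_perp_list),
                   dimnames = list(theta = NULL, rho = NULL))
  for (k in seq_along(d_perp_list)) {
    cfg <- config
    cfg$d_perp <- d_perp_list[k]
    for (it in seq_along(theta_grid)) {
      cfg$theta <- theta_grid[it]
      tv <- tryCatch({
        sol <- solve_force_density(place_rods(cfg, disc))
        rod_torque_z(sol)$mean_torque
      }, error = function(e)
        stop_domain(sprintf("screening solve failed at theta = %.3f, rho = %.3f: %s",
                            theta_grid[it], rho[k], conditionMessage(e))))
      torque[it, k] <- tv
      if (progress)
        message(sprintf("theta = %.3f  d_perp = %.2f  rho = %.3f  T/T0 = %.3f",
                        theta_grid[it], d_perp_list[k], rho[k], tv / t0))
    }
  }
  structure(list(theta_grid = theta_grid, rho_grid = rho,
                 d_perp_list = d_perp_list,
                 normalized_torque = torque / t0, torque = torque,
                 isolated_reference = t0,
                 n_rods = config$n_rows * config$n_cols,
                 segments_per_rod = disc$segments_per_rod,
                 d_par = config$d_par, a_top = a_top),
            class = "screening_table")
}

#' @export
print.screening_table <- function(x, ...) {
  cat(sprintf("Screening table: %d angles x %d densities, %d rods, T0 = %.3f\n",
              length(x$theta_grid), length(x$rho_grid), x$n_rods,
              x$isolated_reference))
  m <- round(x$normalized_torque, 3)
  dimnames(m) <- list(theta = sprintf("%.3f", x$theta_grid),
                      rho = sprintf("%.3f", x$rho_grid))
  print(m)
  invisible(x)
}

#' Read / write screening tables
#'
#' CSV serialisation is long-format with columns `theta_rad`, `rho`,
#' `torque_normalized`; JSON carries the full object with metadata
#' (`n_rods`, `segments_per_rod`, spacings, reference torque).
#'
#' @param table a [screening_sweep()] result.
#' @param path output path, `.csv` or `.json`.
#' @return `read_screening_table()` returns a `screening_table`;
#'   `write_screening_table()` returns `path` invisibly.
#' @export
write_screening_table <- function(table, path) {
  stopifnot(inherits(table, "screening_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # matrices serialise as nested row arrays and read back with their shape
    jsonlite::write_json(unclass(table), path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- data.frame(
      theta_rad = rep(table$theta_grid, times = length(table$rho_grid)),
      rho = rep(table$rho_grid, each = length(table$theta_grid)),
      torque_normalized = as.vector(table$normalized_torque))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_screening_table
#' @param isolated_reference reference torque \eqn{T_0(\pi/2)} to attach when
#'   reading the CSV form (which stores only normalised values).
#' @export
read_screening_table <- function(path, isolated_reference = NA_real_) {
  as_theta_by_rho <- function(x, n_theta) {
    if (is.matrix(x)) return(if (nrow(x) == n_theta) x else t(x))
    matrix(unlist(x), nrow = n_theta)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    nth <- length(x$theta_grid)
    x$normalized_torque <- as_theta_by_rho(x$normalized_torque, nth)
    x$torque <- as_theta_by_rho(x$torque, nth)
    return(structure(x, class = "screening_table"))
  }
  df <- read.csv(path)
  th <- sort(unique(df$theta_rad)); rho <- unique(df$rho)
  nt <- matrix(NA_real_, length(th), length(rho))
  nt[cbind(match(df$theta_rad, th), match(df$rho, rho))] <- df$torque_normalized
  structure(list(theta_grid = th, rho_grid = rho,
                 normalized_torque = nt,
                 torque = nt * isolated_reference,
                 isolated_reference = isolated_reference),
            class = "screening_table")
}
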