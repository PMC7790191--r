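#' Alignment parameter and net cilia-driven flow
#'
#' The alignment parameter is the mean projection of per-cell unit beating
#' directions onto the previously applied flow direction,
#' \eqn{\Phi = (1/N) \sum_i \hat p_i \cdot \hat e}: 1 for complete
#' alignment, 0 for randomly oriented beating. The net flow is the mean
#' projected cilia-driven velocity \eqn{\bar V = (1/N)\sum_i v_i \cdot \hat e}
#' (um/s). An alternative convention, the magnitude of the mean direction
#' vector (which ignores \eqn{\hat e}), is available via `method`.
#'
#' With a `fov` grouping, \eqn{\Phi} is computed per field of view and
#' summarised by its across-FOV mean and standard error.
#'
#' @param records a `cell_records` data frame (columns `px`, `py`,
#'   `vx_um_s`, `vy_um_s`), or any data frame with those columns; rows with
#'   zero velocity are excluded and counted.
#' @param e_hat unit vector of the applied-flow direction (length 2).
#' @param fov optional vector of per-record field-of-view identifiers.
#' @param method `"projection"` (default) or `"vector_mean"`.
#' @return A list of class `alignment_result`: `phi`, `net_flow`,
#'   `n_boxes`, `n_excluded`, and with grouping `per_fov` (data frame),
#'   `phi_sem`, `n_fov`.
#' @export
alignment_parameter <- function(records, e_hat = c(1, 0), fov = NULL,
                                method = c("projection", "vector_mean")) {
  method <- match.arg(method)
  stopifnot(length(e_hat) == 2, all(is.finite(e_hat)))
  nrm <- sqrt(sum(e_hat^2))
  if (nrm == 0) stop_domain("e_hat must be a non-zero vector")
  e_hat <- e_hat / nrm
  df <- as.data.frame(records)
  need <- c("px", "py", "vx_um_s", "vy_um_s")
  if (!all(need %in% names(df)))
    stop_domain("records must have columns ", paste(need, collapse = ", "))
  speed <- sqrt(df$vx_um_s^2 + df$vy_um_s^2)
  keep <- is.finite(speed) & speed > 0
  n_excl <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!is.null(fov)) fov <- fov[keep]
  if (nrow(df) == 0L) stop_domain("no records with non-zero velocity")
  proj <- function(d) {
    if (method == "projection")
      mean(d$px * e_hat[1] + d$py * e_hat[2])
    else
      sqrt(mean(d$px)^2 + mean(d$py)^2)
  }
  vbar <- mean(df$vx_um_s * e_hat[1] + df$vy_um_s * e_hat[2])
  out <- list(phi = proj(df), net_flow = vbar, n_boxes = nrow(df),
              n_excluded = n_excl, e_hat = e_hat, method = method)
  if (!is.null(fov)) {
    per <- vapply(split(df, fov), proj, numeric(1))
    out$per_fov <- data.frame(fov = names(per), phi = as.numeric(per),
                              row.names = NULL)
    out$phi <- mean(per)
    out$phi_sem <- sd(per) / sqrt(length(per))
    out$n_fov <- length(per)
  }
  structure(out, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Alignment: Phi = %.3f", x$phi))
  if (!is.null(x$phi_sem)) cat(sprintf(" +/- %.3f (SEM over %d FOVs)",
                                       x$phi_sem, x$n_fov))
  cat(sprintf("\n  net flow %.2f um/s along e_hat; N = %d boxes (%d excluded)\n",
              x$net_flow, x$n_boxes, x$n_excluded))
  invisible(x)
}

#' Ciliated-cell density metrics
#'
#' From the count of boxes containing ciliated cells, `n_box`, out of the
#' `n_tot` boxes tiling the field of view: the ciliated area fraction
#' \eqn{\rho = N_{box}/N_{tot}} and the ciliated-cell density
#' \eqn{\rho_{cell} = N_{box}/(N_{tot} A_{box})}, converted to cells per
#' square millimetre.
#'
#' @param n_box number of boxes with identified ciliated cells.
#' @param n_tot total number of boxes in the field of view.
#' @param a_box_um2 box area in um^2 (default `7.6^2`).
#' @return A list of class `density_result`: `rho`, `rho_cell_mm2`,
#'   `n_box`, `n_tot`, `a_box_um2`.
#' @export
density_metrics <- function(n_box, n_tot, a_box_um2 = 7.6^2) {
  if (n_tot <= 0) stop_domain("n_tot must be positive")
  stopifnot(n_box >= 0, n_box <= n_tot, a_box_um2 > 0)
  rho <- n_box / n_tot
  structure(list(rho = rho, rho_cell_mm2 = rho / a_box_um2 * 1e6,
                 n_box = n_box, n_tot = n_tot, a_box_um2 = a_box_um2),
            class = "density_result")
}

#' Tapered-channel geometry
#'
#' A channel of constant height `h_mm` whose width grows linearly,
#' \eqn{w(x) = w_0 + \mathrm{slope}\, x}, carries flow rate `q_mm3_s` of a
#' fluid with viscosity `eta_pa_s`. The wall shear stress decays
#' hyperbolically along the channel as the width opens up, so one chip
#' applies a range of stresses to the same culture.
#'
#' @param w0_mm entrance width, mm.
#' @param w_max_mm exit width, mm.
#' @param l_mm length of the tapered section, mm.
#' @param h_mm channel height, mm.
#' @param q_mm3_s flow rate, mm^3/s.
#' @param eta_pa_s fluid viscosity, Pa s (default 0.8 mPa s for culture
#'   medium at 37 C; always echoed in outputs).
#' @return An object of class `channel_geometry` (fields include the taper
#'   `slope` in mm per mm).
#' @export
channel_geometry <- function(w0_mm = 1, w_max_mm = 5, l_mm = 7, h_mm = 1,
                             q_mm3_s = 1, eta_pa_s = 0.8e-3) {
  stopifnot(w0_mm > 0, w_max_mm >= w0_mm, l_mm > 0, h_mm > 0,
            q_mm3_s >= 0, eta_pa_s > 0)
  structure(list(w0_mm = w0_mm, w_max_mm = w_max_mm, l_mm = l_mm,
                 h_mm = h_mm, slope = (w_max_mm - w0_mm) / l_mm,
                 q_mm3_s = q_mm3_s, eta_pa_s = eta_pa_s),
            class = "channel_geometry")
}

#' Wall shear stress along a tapered channel
#'
#' \eqn{\tau(x) = 6 \eta Q / (h^2 w(x))} with
#' \eqn{w(x) = w_0 + \mathrm{slope}\,x}, returned in dyne/cm^2
#' (1 Pa = 10 dyne/cm^2). With the default geometry (entrance width 1 mm
#' opening to 5 mm over 7 mm) the entrance stress is exactly five times the
#' exit stress.
#'
#' @param geom a [channel_geometry()].
#' @param x_mm axial position(s), mm, in `[0, l_mm]`.
#' @return Shear stress in dyne/cm^2, vectorised over `x_mm`.
#' @export
shear_profile <- function(geom, x_mm) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (any(x_mm < 0 | x_mm > geom$l_mm))
    stop_domain("x_mm outside the channel [0, l]")
  w <- geom$w0_mm + geom$slope * x_mm
  tau_pa <- 6 * geom$eta_pa_s * geom$q_mm3_s / (geom$h_mm^2 * w)
  10 * tau_pa
}

#' Wall shear stress from a measured near-wall flow
#'
#' The shear stress that a flow of speed `v_um_s` at height `h_um` above the
#' wall exerts on the surface, \eqn{\tau_0 = \eta V / h}, in dyne/cm^2. The
#' canonical worked example -- a cilia-driven flow of 50 um/s measured 20 um
#' above the cell layer in medium of viscosity 0.8 mPa s -- gives
#' 0.02 dyne/cm^2.
#'
#' @param v_um_s flow speed, um/s.
#' @param h_um measurement height above the wall, um.
#' @param eta_pa_s viscosity, Pa s.
#' @return Shear stress, dyne/cm^2.
#' @export
wall_shear_from_flow <- function(v_um_s, h_um, eta_pa_s = 0.8e-3) {
  stopifnot(v_um_s >= 0, h_um > 0, eta_pa_s > 0)
  10 * eta_pa_s * (v_um_s / h_um)    # (um/s)/um = 1/s; Pa -> dyne/cm^2
}

# sum of squared residuals of the saturating-exponential dose-response
dose_sse <- function(log_tau_c, tau, phi) {
  tc <- exp(log_tau_c)
  sum((phi - (1 - exp(-tau / tc)))^2)
}

# single NLS fit of tau_c by Brent minimisation of the SSE profile
fit_tau_c_once <- function(tau, phi) {
  lo <- log(min(tau) / 100); hi <- log(max(tau) * 100)
  opt <- optimize(dose_sse, c(lo, hi), tau = tau, phi = phi, tol = 1e-12)
  exp(opt$minimum)
}

#' Fit the alignment dose-response and extract the critical shear stress
#'
#' Fits the saturating exponential \eqn{\Phi = 1 - \exp(-\tau/\tau_c)} to
#' (shear stress, alignment) pairs by nonlinear least squares (Brent search
#' on the one-parameter sum-of-squares profile). \eqn{\tau_c} is the
#' critical shear stress at which the fitted alignment reaches
#' \eqn{1 - e^{-1} \approx 0.632}. The 68% confidence interval comes from a
#' seeded case-resampling bootstrap.
#'
#' @param tau shear stresses, dyne/cm^2, all positive (>= 3 values).
#' @param phi alignment values; entries above 1 are clipped with a warning.
#' @param n_boot bootstrap draws (default 500; 0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.68).
#' @return A list of class `dose_response_fit`: `tau_c`, `ci` (length 2),
#'   `phi_at_tau_c` (\eqn{1 - e^{-1}}), `fitted` (data frame `tau`, `phi`),
#'   `residuals`, `n`, `n_boot`.
#' @export
fit_dose_response <- function(tau, phi, n_boot = 500, seed = 1, conf = 0.68) {
  stopifnot(length(tau) == length(phi))
  ok <- is.finite(tau) & is.finite(phi)
  tau <- tau[ok]; phi <- phi[ok]
  if (length(tau) < 3L) stop_domain("need at least 3 (tau, phi) pairs")
  if (any(tau <= 0)) stop_domain("all tau must be positive")
  if (any(phi > 1)) {
    warning(sprintf("%d phi values above 1 clipped", sum(phi > 1)))
    phi <- pmin(phi, 1)
  }
  tc <- fit_tau_c_once(tau, phi)
  fitted_phi <- 1 - exp(-tau / tc)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    n <- length(tau)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      fit_tau_c_once(tau[i], phi[i])
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  structure(list(tau_c = tc, ci = ci, phi_at_tau_c = 1 - exp(-1),
                 fitted = data.frame(tau = tau, phi = fitted_phi),
                 residuals = phi - fitted_phi, n = length(tau),
                 n_boot = n_boot, conf = conf),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: tau_c = %.4g dyne/cm^2", x$tau_c))
  if (all(is.finite(x$ci)))
    cat(sprintf(" (%d%% CI %.4g - %.4g)", round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("\n  Phi at tau_c: %.3f; n = %d points\n", x$phi_at_tau_c, x$n))
  invisible(x)
}

#' Read a condition manifest
#'
#' A YAML manifest lists experimental conditions (chip, days in vitro,
#' applied shear stress, channel-segment position) and the per-FOV record
#' CSVs belonging to each.
#'
#' @param path YAML file path.
#' @return The parsed list.
#' @export
read_condition_manifest <- function(path) {
  yaml::read_yaml(path)
}
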