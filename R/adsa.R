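# Axisymmetric drop shape analysis (ADSA) for the constrained (sessile,
# pedestal-mounted) drop: forward integration of the Young-Laplace shape
# equations and inverse recovery of surface tension from an observed contour.
#
# Shape system in arc length s from the apex (z measured from the apex into
# the drop, so hydrostatic pressure increases with z for delta_rho > 0):
#   dphi/ds = 2/R0 + (delta_rho*g/gamma) * z - sin(phi)/r
#   dr/ds   = cos(phi)
#   dz/ds   = sin(phi)
# with the apex limit dphi/ds -> 1/R0 as s -> 0. Integration starts a short
# step off the apex using the series expansion of the spherical solution to
# avoid the sin(phi)/r singularity, and stops where r first reaches the
# pedestal radius (the knife-edge boundary of the constrained drop).

#' Physical parameters of an axisymmetric drop
#'
#' @param gamma Surface tension, mN/m (> 0).
#' @param delta_rho Density difference between drop and surrounding phase,
#'   kg/m^3 (>= 0; 0 gives a spherical drop).
#' @param apex_radius Radius of curvature at the apex, mm (> 0).
#' @param pedestal_radius Radius of the knife-edge pedestal at which the
#'   contour terminates, mm (> 0).
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @return An object of class \code{physical_params} with a precomputed Bond
#'   number.
#' @export
physical_params <- function(gamma, delta_rho, apex_radius, pedestal_radius,
                            g = 9.81) {
  if (!is.finite(gamma) || gamma <= 0)
    stop_cdsurf("surface tension must be positive and finite", "parameter_error")
  if (!is.finite(delta_rho) || delta_rho < 0)
    stop_cdsurf("density difference must be >= 0", "parameter_error")
  if (!is.finite(apex_radius) || apex_radius <= 0)
    stop_cdsurf("apex radius must be positive", "parameter_error")
  if (!is.finite(pedestal_radius) || pedestal_radius <= 0)
    stop_cdsurf("pedestal radius must be positive", "parameter_error")
  beta <- bond_number(delta_rho, g, apex_radius, gamma)
  if (!is.finite(beta))
    stop_cdsurf("Bond number is not finite", "parameter_error")
  structure(
    list(gamma = gamma, delta_rho = delta_rho, g = g,
         apex_radius = apex_radius, pedestal_radius = pedestal_radius,
         bond = beta),
    class = "physical_params"
  )
}

# Right-hand side of the shape system; y = (phi, r, z).
yl_rhs <- function(s, y, parms) {
  phi <- y[1]; r <- y[2]; z <- y[3]
  curv <- if (r > parms$r_eps) {
    2 / parms$R0 + parms$kappa * z - sin(phi) / r
  } else {
    # apex limit: sin(phi)/r -> 1/R0
    1 / parms$R0 + parms$kappa * z
  }
  list(c(curv, cos(phi), sin(phi)))
}

#' Integrate the Young-Laplace drop profile
#'
#' Forward model of the drop contour: integrates the axisymmetric shape
#' equations from the apex until the profile first reaches the pedestal
#' radius, using an adaptive solver with root detection and a series start at
#' the apex.
#'
#' @param params A \code{\link{physical_params}} object.
#' @param step Arc-length output spacing, mm (> 0). Controls sampling density
#'   of the returned contour, not solver accuracy (the solver is adaptive
#'   with tight tolerances).
#' @param max_arc_factor Give up (geometry error) if the contour has not
#'   reached the pedestal radius within \code{max_arc_factor * apex_radius}
#'   of arc length.
#' @return A \code{drop_profile}: data frame with columns \code{s} (arc
#'   length, mm), \code{r}, \code{z} (mm), \code{phi} (turning angle, rad);
#'   first row is the apex (0, 0, 0, 0), last row lies on the pedestal
#'   radius. The generating parameters are attached as attribute
#'   \code{"params"}.
#' @export
integrate_drop_profile <- function(params, step = params$apex_radius / 200,
                                   max_arc_factor = 30) {
  if (!inherits(params, "physical_params"))
    stop_cdsurf("params must be a physical_params object", "parameter_error")
  if (!is.finite(step) || step <= 0)
    stop_cdsurf("step must be positive", "parameter_error")
  R0 <- params$apex_radius
  kappa <- capillary_constant_mm2(params$delta_rho, params$g, params$gamma)
  rped <- params$pedestal_radius
  max_s <- max_arc_factor * R0

  # series start just off the apex (spherical to leading order):
  # phi = s/R0 + O(s^3), r = s - s^3/(6 R0^2), z = s^2/(2 R0)
  s0 <- min(step / 4, 1e-4 * R0)
  y0 <- c(phi = s0 / R0, r = s0 - s0^3 / (6 * R0^2), z = s0^2 / (2 * R0))

  times <- unique(c(s0, seq(s0, max_s, by = step), max_s))
  sol <- deSolve::lsodar(
    y = y0, times = times, func = yl_rhs,
    parms = list(R0 = R0, kappa = kappa, r_eps = 1e-9 * R0),
    # stop at the pedestal radius, or when the contour closes up (phi = pi)
    # without ever reaching it -- then the pedestal is wider than the drop
    rootfunc = function(s, y, parms) c(y[2] - rped, y[1] - pi),
    rtol = 1e-10, atol = 1e-12
  )
  sol <- as.data.frame(sol)
  names(sol) <- c("s", "phi", "r", "z")
  reached <- abs(sol$r[nrow(sol)] - rped) <= 1e-6 * rped
  if (!reached)
    stop_cdsurf(
      "profile did not reach the pedestal radius within the allowed arc length",
      "geometry_error")

  prof <- rbind(data.frame(s = 0, r = 0, z = 0, phi = 0),
                sol[, c("s", "r", "z", "phi")])
  structure(prof, params = params, class = c("drop_profile", "data.frame"))
}

#' Surface area and volume of a drop contour
#'
#' Surface-of-revolution quadrature over the contour: area
#' \eqn{2\pi \int r\,ds} and volume \eqn{\pi \int r^2\,dz} (trapezoid rule).
#'
#' @param profile A \code{drop_profile} or data frame with columns
#'   \code{s}, \code{r}, \code{z} (mm).
#' @return Named list: \code{area} (mm^2) and \code{volume} (uL; 1 mm^3 is
#'   reported as 1 uL).
#' @export
profile_area_volume <- function(profile) {
  if (nrow(profile) < 3)
    stop_cdsurf("need at least 3 contour points", "insufficient_data_error")
  area <- 2 * pi * pracma::trapz(profile$s, profile$r)
  volume <- pi * pracma::trapz(profile$z, profile$r^2)
  list(area = area, volume = volume)
}

# Squared nearest-neighbour distances from observed (r, z) points to a
# densely sampled forward contour, measured point-to-segment (projection onto
# the polyline) so the metric is free of discretization bias. The nearest
# segment is located via the nearest vertex (the curve is smooth and sampled
# far below its curvature scale, so the nearest segment is adjacent to the
# nearest vertex); a small window of neighbouring segments guards the edge
# cases, and the vertex search is chunked to keep the distance matrix small.
nn_sq_dist <- function(obs_r, obs_z, cur_r, cur_z) {
  k <- length(cur_r)
  m <- length(obs_r)
  nearest <- integer(m)
  chunk <- 512L
  for (start in seq.int(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    d2 <- outer(obs_r[idx], cur_r, "-")^2 + outer(obs_z[idx], cur_z, "-")^2
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  out <- rep(Inf, m)
  for (off in -3:2) {
    j <- pmin(pmax(nearest + off, 1L), k - 1L)
    ex <- cur_r[j + 1L] - cur_r[j]; ey <- cur_z[j + 1L] - cur_z[j]
    len2 <- pmax(ex^2 + ey^2, .Machine$double.eps)
    dx <- obs_r - cur_r[j]; dy <- obs_z - cur_z[j]
    tt <- pmin(pmax((dx * ex + dy * ey) / len2, 0), 1)
    px <- dx - tt * ex; py <- dy - tt * ey
    out <- pmin(out, px^2 + py^2)
  }
  out
}

#' Fit surface tension to an observed drop contour (ADSA inverse step)
#'
#' Recovers surface tension (and apex radius) by least squares between the
#' observed contour points and the forward-integrated Young-Laplace profile.
#' The distance metric is point-to-curve nearest-neighbour distance against a
#' densely sampled forward profile; the observed contour is assumed
#' apex-aligned (apex at the origin, axis vertical), with apex detection
#' treated as upstream preprocessing.
#'
#' @param observed Data frame with columns \code{r}, \code{z} (mm), >= 20
#'   points, apex-aligned.
#' @param delta_rho Density difference, kg/m^3 (> 0: at zero Bond number the
#'   shape carries no surface-tension information).
#' @param g Gravitational acceleration, m/s^2.
#' @param init Optional named list with starting values \code{gamma} (mN/m)
#'   and \code{apex_radius} (mm); estimated from the contour when omitted.
#' @param dense_n Number of arc-length samples of the forward profile used
#'   for the nearest-neighbour metric in the search stage; the refinement
#'   stage uses 8x this density (the chord error of the polyline scales as
#'   the squared spacing, so the refined stage resolves gamma to well below
#'   0.1 percent).
#' @param refine Run the dense refinement stage (default TRUE). The
#'   refinement removes the polyline chord bias of order (contour
#'   spacing)^2/8 ~ 1e-5 mm; with coordinate noise of 1 um or more that bias
#'   is negligible against the noise floor and the stage can be skipped for
#'   speed.
#' @return List: \code{gamma} (mN/m), \code{apex_radius} (mm),
#'   \code{residual} (RMS point-to-curve distance, mm; the quality measure to
#'   inspect), \code{n_points}, \code{convergence} (raw \code{optim} code of
#'   the last stage; 1 merely means the iteration budget was used in full,
#'   which is routine for the refinement stage).
#' @export
fit_surface_tension <- function(observed, delta_rho, g = 9.81, init = NULL,
                                dense_n = 400, refine = TRUE) {
  observed <- as.data.frame(observed)
  if (!all(c("r", "z") %in% names(observed)))
    stop_cdsurf("observed contour needs columns r and z", "parameter_error")
  if (nrow(observed) < 20)
    stop_cdsurf("need at least 20 contour points for a stable fit",
                "parameter_error")
  if (!is.finite(delta_rho) || delta_rho <= 0)
    stop_cdsurf(
      "delta_rho must be > 0: at zero Bond number the drop shape is spherical for every surface tension (identifiability error)",
      "identifiability_error")

  # drop the apex point itself if present (zero information, and it is the
  # alignment anchor, not data)
  keep <- !(observed$r == 0 & observed$z == 0)
  obs_r <- observed$r[keep]; obs_z <- observed$z[keep]
  r_edge <- max(obs_r)

  # forward contour for the metric: integrate until the curve extends just
  # past the observed point cloud (polar radius from the apex), so the
  # comparison curve always covers the data regardless of candidate params
  rho_max <- 1.02 * sqrt(max(obs_r^2 + obs_z^2))
  fwd_contour <- function(gamma, R0, n_samples) {
    kappa <- capillary_constant_mm2(delta_rho, g, gamma)
    s0 <- 1e-5 * R0
    y0 <- c(phi = s0 / R0, r = s0 - s0^3 / (6 * R0^2), z = s0^2 / (2 * R0))
    smax <- 3 * rho_max + 2 * R0
    times <- seq(s0, smax, length.out = n_samples)
    sol <- deSolve::lsodar(
      y = y0, times = times, func = yl_rhs,
      parms = list(R0 = R0, kappa = kappa, r_eps = 1e-9 * R0),
      rootfunc = function(s, y, parms)
        c(y[2]^2 + y[3]^2 - rho_max^2, y[1] - pi),
      rtol = 1e-9, atol = 1e-11)
    list(r = c(0, sol[, 3]), z = c(0, sol[, 4]))
  }
  make_objective <- function(n_samples) {
    function(par) {
      gamma <- exp(par[1]); R0 <- exp(par[2])
      prof <- tryCatch(fwd_contour(gamma, R0, n_samples),
                       error = function(e) NULL)
      if (is.null(prof) || length(prof$r) < 5) return(1e6 * r_edge^2)
      mean(nn_sq_dist(obs_r, obs_z, prof$r, prof$z))
    }
  }
  objective <- make_objective(dense_n)

  if (is.null(init)) {
    # apex radius from the parabolic apex approximation z ~ r^2 / (2 R0)
    near <- obs_r <= 0.5 * r_edge & obs_z > 0
    R0_init <- if (any(near)) stats::median(obs_r[near]^2 / (2 * obs_z[near]))
               else r_edge
    R0_init <- max(R0_init, 0.2 * r_edge)
    # coarse surface-tension grid, spanning Bond numbers ~0.02-20 at R0_init
    beta_grid <- c(0.02, 0.05, 0.15, 0.5, 1.5, 5, 20)
    gam_grid <- delta_rho * g * R0_init^2 * 1e-3 / beta_grid
    obj_grid <- vapply(gam_grid,
                       function(gam) objective(log(c(gam, R0_init))),
                       numeric(1))
    init <- list(gamma = gam_grid[which.min(obj_grid)], apex_radius = R0_init)
  }

  fit <- stats::optim(log(c(init$gamma, init$apex_radius)), objective,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 300))
  if (refine) {
    # restart from the optimum against a much denser forward contour,
    # removing the polyline chord bias that limits the first stage
    fine <- make_objective(8 * dense_n)
    fit <- stats::optim(fit$par, fine, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 120,
                                       parscale = c(0.02, 0.02)))
  }
  if (!is.finite(fit$value) || fit$value >= 1e5 * r_edge^2)
    stop_cdsurf("ADSA fit failed to converge to a feasible drop shape",
                "fit_failure_error")
  list(gamma = exp(fit$par[1]),
       apex_radius = exp(fit$par[2]),
       residual = sqrt(fit$value),
       n_points = length(obs_r),
       convergence = fit$convergence)
}
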