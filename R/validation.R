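# Self-validation studies for the ADSA inverse step. These define the study
# conditions used by the test suite and the analysis scripts: a water-like
# drop (delta_rho = 1000 kg/m^3) with 1 mm apex radius, truncated just below
# its equator (constrained drops are run near maximum volume, where the
# contour approaches the equatorial plane), imaged as an apex-aligned contour
# sampled at sub-micron spacing with 1 um i.i.d. Gaussian coordinate noise.

#' Equatorial radius of a drop
#'
#' Maximum horizontal radius of the axisymmetric drop (where the turning
#' angle reaches 90 degrees), used to place the pedestal below the bulge.
#'
#' @inheritParams physical_params
#' @return Equator radius, mm.
#' @export
drop_equator_radius <- function(gamma, delta_rho, apex_radius, g = 9.81) {
  kappa <- capillary_constant_mm2(delta_rho, g, gamma)
  s0 <- 1e-5 * apex_radius
  y0 <- c(phi = s0 / apex_radius, r = s0, z = s0^2 / (2 * apex_radius))
  sol <- deSolve::lsodar(
    y = y0, times = seq(s0, 10 * apex_radius, length.out = 2000),
    func = yl_rhs, parms = list(R0 = apex_radius, kappa = kappa,
                                r_eps = 1e-9 * apex_radius),
    rootfunc = function(s, y, parms) y[1] - pi / 2,
    rtol = 1e-9, atol = 1e-11)
  max(sol[, 3])
}

#' Round-trip validation study for the ADSA fit
#'
#' For each Bond number, generates a forward drop contour (apex radius 1 mm,
#' water-like density difference, pedestal at 97 percent of the equator
#' radius), then (a) refits the noiseless contour and (b) refits
#' \code{n_noise_seeds} noisy copies with i.i.d. Gaussian coordinate noise,
#' reporting relative surface-tension recovery errors.
#'
#' @param betas Bond numbers of the study grid.
#' @param n_noise_seeds Noisy replicates per Bond number (0 to skip).
#' @param noise_sd Coordinate noise, mm (default 1e-3 = 1 um).
#' @param contour_step Arc-length spacing of the observed contour, mm.
#' @param seed Base RNG seed; replicate j of Bond-number i uses
#'   \code{seed + 1000*i + j}.
#' @param delta_rho,g Drop physical constants.
#' @return List with data frames \code{noiseless} (beta, gamma_true,
#'   gamma_fit, rel_error) and \code{noisy} (beta, seed, gamma_true,
#'   gamma_fit, rel_error).
#' @export
adsa_roundtrip_study <- function(betas = c(0.05, 0.2, 0.5, 1, 2),
                                 n_noise_seeds = 20, noise_sd = 1e-3,
                                 contour_step = 7.5e-4, seed = 1,
                                 delta_rho = 1000, g = 9.81) {
  R0 <- 1
  noiseless <- NULL
  noisy <- NULL
  for (i in seq_along(betas)) {
    beta <- betas[i]
    gamma <- delta_rho * g * R0^2 * 1e-3 / beta
    ped <- 0.97 * drop_equator_radius(gamma, delta_rho, R0, g)
    prof <- integrate_drop_profile(
      physical_params(gamma, delta_rho, R0, ped, g), step = contour_step)
    contour <- prof[-1, c("r", "z")]

    fit0 <- fit_surface_tension(contour, delta_rho, g)
    noiseless <- rbind(noiseless, data.frame(
      beta = beta, gamma_true = gamma, gamma_fit = fit0$gamma,
      rel_error = abs(fit0$gamma - gamma) / gamma))

    for (j in seq_len(n_noise_seeds)) {
      set.seed(seed + 1000 * i + j)
      obs <- data.frame(
        r = contour$r + stats::rnorm(nrow(contour), 0, noise_sd),
        z = contour$z + stats::rnorm(nrow(contour), 0, noise_sd))
      fitn <- fit_surface_tension(obs, delta_rho, g, refine = FALSE)
      noisy <- rbind(noisy, data.frame(
        beta = beta, seed = seed + 1000 * i + j, gamma_true = gamma,
        gamma_fit = fitn$gamma,
        rel_error = abs(fitn$gamma - gamma) / gamma))
    }
  }
  list(noiseless = noiseless, noisy = noisy)
}
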