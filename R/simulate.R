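# Biophysical film simulator: surface-tension/area traces of a cycling
# surfactant drop with dose-dependent inhibition. The model is
# phenomenological: a functional film reaches a low surface-tension floor at
# maximal compression; continuously deposited inhibitor raises that floor
# along a saturating dose-response, which is what the downstream inhibition
# criteria detect.

#' Cycling protocol of the constrained drop surfactometer
#'
#' @param cycle_rate Compression-expansion cycles per minute (default 20,
#'   mimicking human respiratory cycles).
#' @param frame_rate Imaging frame rate, Hz (default 10).
#' @param baseline_area Fully expanded drop surface area A0, mm^2 (default 18,
#'   the curved surface of a roughly hemispherical 10 uL drop).
#' @param relative_amplitude Fractional area compression per cycle, in (0, 1)
#'   (default 0.25, below the 30 percent acceptance limit).
#' @param duration Trace duration, s.
#' @param temperature Chamber temperature, degrees C (metadata only).
#' @return A \code{cycling_protocol} object.
#' @export
cycling_protocol <- function(cycle_rate = 20, frame_rate = 10,
                             baseline_area = 18, relative_amplitude = 0.25,
                             duration = 60, temperature = 37) {
  if (relative_amplitude <= 0 || relative_amplitude >= 1)
    stop_cdsurf("relative_amplitude must be in (0, 1)", "parameter_error")
  if (frame_rate * 60 / cycle_rate < 10)
    stop_cdsurf("need at least 10 frames per cycle", "parameter_error")
  if (baseline_area <= 0 || duration <= 0)
    stop_cdsurf("baseline_area and duration must be positive",
                "parameter_error")
  structure(list(cycle_rate = cycle_rate, frame_rate = frame_rate,
                 baseline_area = baseline_area,
                 relative_amplitude = relative_amplitude,
                 duration = duration, temperature = temperature),
            class = "cycling_protocol")
}

#' Film model parameters
#'
#' Phenomenological dose-response of surfactant inhibition. The per-cycle
#' surface-tension floor rises from \code{gamma_floor_functional} (a working
#' film, below the 5 mN/m acceptance limit) towards
#' \code{gamma_floor_inhibited} (a dysfunctional film, above the 10 mN/m
#' inhibition threshold) as deposited dose accumulates, with half-maximal
#' effect at dose \code{d50}.
#'
#' @param gamma_max Surface tension at full expansion, mN/m (default 40).
#' @param gamma_floor_functional Floor of the uninhibited film, mN/m
#'   (default 2; must be < 5).
#' @param gamma_floor_inhibited Asymptotic floor at saturating dose, mN/m
#'   (default 25; must be >= 10 and < gamma_max).
#' @param d50 Dose at half-maximal inhibition, ng/cm^2 (default 100).
#' @param deposition_flux Aerosol deposition flux J, ng/cm^2/min (default 0 =
#'   no test chemical).
#' @param compression_exponent Shape exponent of the within-cycle
#'   compression response (default 1).
#' @param noise_sd Gaussian measurement noise on surface tension, mN/m
#'   (default 0.3).
#' @param seed RNG seed for the noise (default NULL: leave RNG state alone).
#' @return A \code{film_params} object.
#' @export
film_params <- function(gamma_max = 40, gamma_floor_functional = 2,
                        gamma_floor_inhibited = 25, d50 = 100,
                        deposition_flux = 0, compression_exponent = 1,
                        noise_sd = 0.3, seed = NULL) {
  if (!(gamma_floor_functional < 5))
    stop_cdsurf("functional floor must be below 5 mN/m", "parameter_error")
  if (!(gamma_floor_inhibited >= 10 && gamma_floor_inhibited < gamma_max))
    stop_cdsurf("inhibited floor must be >= 10 mN/m and below gamma_max",
                "parameter_error")
  if (d50 <= 0) stop_cdsurf("d50 must be positive", "parameter_error")
  if (deposition_flux < 0)
    stop_cdsurf("deposition flux must be >= 0", "parameter_error")
  if (noise_sd < 0) stop_cdsurf("noise_sd must be >= 0", "parameter_error")
  structure(list(gamma_max = gamma_max,
                 gamma_floor_functional = gamma_floor_functional,
                 gamma_floor_inhibited = gamma_floor_inhibited,
                 d50 = d50, deposition_flux = deposition_flux,
                 compression_exponent = compression_exponent,
                 noise_sd = noise_sd, seed = seed),
            class = "film_params")
}

#' Simulated drop area series
#'
#' Sinusoidal pump-driven area cycling:
#' \eqn{A(t) = A_0 (1 - a/2 + (a/2) \cos(2\pi f t))}, so the maximum area is
#' \eqn{A_0} and every cycle's compression ratio is exactly the relative
#' amplitude \eqn{a}.
#'
#' @param protocol A \code{\link{cycling_protocol}}.
#' @return Data frame with \code{time_s} and \code{area_mm2}, one row per
#'   frame.
#' @export
simulate_area <- function(protocol) {
  n <- round(protocol$duration * protocol$frame_rate)
  t <- (seq_len(n) - 1) / protocol$frame_rate
  f <- protocol$cycle_rate / 60
  a <- protocol$relative_amplitude
  A <- protocol$baseline_area * (1 - a / 2 + (a / 2) * cos(2 * pi * f * t))
  data.frame(time_s = t, area_mm2 = A)
}

#' Analytic time at which the inhibition floor crosses a threshold
#'
#' Solves \eqn{\gamma_{floor}(t) = \gamma^*} for the saturating dose-response
#' with cumulative dose \eqn{D(t) = J t}. Returns Inf when the asymptotic
#' floor never reaches the threshold (e.g. J = 0).
#'
#' @param film A \code{\link{film_params}}.
#' @param threshold Surface tension threshold, mN/m (default 10, the
#'   inhibition criterion).
#' @return Crossing time in seconds (Inf if never crossed).
#' @export
floor_crossing_time <- function(film, threshold = 10) {
  g0 <- film$gamma_floor_functional
  g1 <- film$gamma_floor_inhibited
  if (film$deposition_flux <= 0 || threshold >= g1 || threshold <= g0)
    return(if (threshold <= g0) 0 else Inf)
  dose <- film$d50 * (threshold - g0) / (g1 - threshold)
  dose / film$deposition_flux * 60
}

#' Simulate a surface-tension/area trace
#'
#' Combines the pump-driven area cycling with the film dose-response:
#' cumulative dose \eqn{D(t) = J t}, floor
#' \eqn{\gamma_f(t) = \gamma_{f0} + (\gamma_{f\infty} - \gamma_{f0})
#' D/(D + D_{50})}, and instantaneous
#' \eqn{\gamma(t) = \gamma_f(t) + (\gamma_{max} - \gamma_f(t)) (1 - c(t))^p
#' + \epsilon}, where \eqn{c(t) \in [0, 1]} is the normalized within-cycle
#' compression (1 at maximal compression) and \eqn{\epsilon} is i.i.d.
#' Gaussian noise. Area is noise-free (pump-controlled); surface tension is
#' the measured quantity.
#'
#' @param protocol A \code{\link{cycling_protocol}}.
#' @param film A \code{\link{film_params}}.
#' @param chemical_id,replicate_id Optional metadata recorded on the trace.
#' @return A \code{st_trace}: data frame with \code{time_s},
#'   \code{gamma_mN_per_m}, \code{area_mm2}, with the protocol, film
#'   parameters and ids attached as attributes.
#' @export
simulate_trace <- function(protocol, film, chemical_id = NA_character_,
                           replicate_id = NA_integer_) {
  ar <- simulate_area(protocol)
  a <- protocol$relative_amplitude
  A0 <- protocol$baseline_area
  comp <- (A0 - ar$area_mm2) / (A0 * a)  # 0 at full expansion, 1 at max compression
  dose <- film$deposition_flux * ar$time_s / 60
  floor <- film$gamma_floor_functional +
    (film$gamma_floor_inhibited - film$gamma_floor_functional) *
      dose / (dose + film$d50)
  gamma <- floor + (film$gamma_max - floor) *
    (1 - comp)^film$compression_exponent
  if (film$noise_sd > 0) {
    if (!is.null(film$seed)) set.seed(film$seed)
    gamma <- gamma + stats::rnorm(length(gamma), 0, film$noise_sd)
  }
  trace <- data.frame(time_s = ar$time_s,
                      gamma_mN_per_m = pmax(gamma, 1e-3),
                      area_mm2 = ar$area_mm2)
  structure(trace, protocol = protocol, film = film,
            chemical_id = chemical_id, replicate_id = replicate_id,
            frame_rate = protocol$frame_rate,
            class = c("st_trace", "data.frame"))
}
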