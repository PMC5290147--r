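#' Acquisition parameters for simulated force-distance curves
#'
#' Bundle of instrument settings used both by the curve generator and as
#' curve metadata. Defaults describe the cell-scale assay: a 0.06 N/m
#' cantilever retracted at 5 um/s over 90 um until cell and substrate are
#' fully separated, a 2 nN contact-force setpoint, and a 10 pN force-noise
#' floor. `retract_distance / retract_speed * sampling_rate` fixes the number
#' of retract samples.
#'
#' @param spring_constant cantilever spring constant, N/m (> 0).
#' @param retract_speed retraction speed, m/s (> 0).
#' @param sampling_rate force sampling rate, Hz (> 0).
#' @param setpoint_force contact-force setpoint, N.
#' @param noise_sd additive Gaussian force noise s.d., N (>= 0).
#' @param drift_slope linear baseline tilt, N per metre of piezo travel.
#' @param temperature bath temperature, K (> 0).
#' @param retract_distance total retract travel, m (> 0).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(spring_constant = 0.06,
                               retract_speed = 5e-6,
                               sampling_rate = 100,
                               setpoint_force = 2e-9,
                               noise_sd = 1e-11,
                               drift_slope = 0,
                               temperature = 310,
                               retract_distance = 9e-5) {
  for (nm in c("spring_constant", "retract_speed", "sampling_rate",
               "setpoint_force", "noise_sd", "drift_slope", "temperature",
               "retract_distance"))
    stop_if_not_scalar_number(get(nm), nm)
  if (spring_constant <= 0) stop("'spring_constant' must be > 0")
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  if (retract_speed <= 0) stop("'retract_speed' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (retract_distance <= 0) stop("'retract_distance' must be > 0")
  structure(list(spring_constant = spring_constant,
                 retract_speed = retract_speed,
                 sampling_rate = sampling_rate,
                 setpoint_force = setpoint_force,
                 noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 temperature = temperature,
                 retract_distance = retract_distance),
            class = "acquisition_params")
}

#' Acquisition preset for single-molecule sensitivity
#'
#' The single-molecule modification of the assay: low contact force (200 pN),
#' near-zero contact time and a short retract. The noise floor is set to
#' 3 pN — the filtered force precision needed for the downstream 5-sigma
#' event rule to resolve the smallest admissible rupture forces (20 pN floor
#' of the rupture-force distribution).
#'
#' @param ... overrides passed to [acquisition_params()].
#' @return An `acquisition_params` object.
#' @export
sm_acquisition_params <- function(...) {
  defaults <- list(setpoint_force = 2e-10, noise_sd = 3e-12,
                   sampling_rate = 2000, retract_distance = 1e-6)
  args <- utils::modifyList(defaults, list(...))
  do.call(acquisition_params, args)
}
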