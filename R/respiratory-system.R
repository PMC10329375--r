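#' Passive respiratory-system model
#'
#' Describes a single-compartment passive respiratory system by its airway
#' resistance, a linear or bilinear static compliance, and optionally an
#' airway opening pressure (AOP) below which the small airways are closed and
#' no gas enters the lung.
#'
#' A bilinear compliance emulates the lower inflection point (LIP) seen on
#' static pressure-volume curves of some ARDS patients: compliance is
#' `c_below` for recoil pressures under `lip` and `c_above` over it.
#'
#' @param rrs Airway resistance, cmH2O/(L/s). Must be positive.
#' @param crs Linear respiratory-system compliance, mL/cmH2O. Supply either
#'   `crs` or the three bilinear parameters.
#' @param c_below,c_above Compliance below / above the lower inflection
#'   point, mL/cmH2O.
#' @param lip Lower inflection point, cmH2O.
#' @param aop Airway opening pressure, cmH2O (absolute airway pressure), or
#'   `NULL` for a system without airway closure.
#' @param relax_volume Lung volume at zero elastic recoil, mL. Only shifts
#'   the absolute volume reference; internal computations use volume above
#'   relaxation.
#'
#' @return An object of class `respiratory_system`.
#' @examples
#' respiratory_system(rrs = 10, crs = 40, aop = 10)
#' respiratory_system(rrs = 10, c_below = 20, c_above = 40, lip = 10)
#' @export
respiratory_system <- function(rrs, crs = NULL, c_below = NULL, c_above = NULL,
                               lip = NULL, aop = NULL, relax_volume = 0) {
  check_number(rrs, "rrs", 0, strict = TRUE)
  bilinear <- is.null(crs)
  if (bilinear) {
    if (is.null(c_below) || is.null(c_above) || is.null(lip)) {
      abort("Supply either `crs` (linear) or all of `c_below`, `c_above`, `lip` (bilinear).")
    }
    check_number(c_below, "c_below", 0, strict = TRUE)
    check_number(c_above, "c_above", 0, strict = TRUE)
    check_number(lip, "lip", 0, strict = TRUE)
  } else {
    if (!is.null(c_below) || !is.null(c_above) || !is.null(lip)) {
      abort("Supply either `crs` or the bilinear parameters, not both.")
    }
    check_number(crs, "crs", 0, strict = TRUE)
  }
  if (!is.null(aop)) check_number(aop, "aop", 0, strict = TRUE)
  check_number(relax_volume, "relax_volume", 0)
  structure(
    list(
      rrs = rrs, bilinear = bilinear,
      crs = if (bilinear) NULL else crs,
      c_below = if (bilinear) c_below else crs,
      c_above = if (bilinear) c_above else crs,
      lip = if (bilinear) lip else Inf,
      aop = aop, relax_volume = relax_volume
    ),
    class = "respiratory_system"
  )
}

#' @export
print.respiratory_system <- function(x, ...) {
  cat("<respiratory_system>\n")
  cat(sprintf("  Rrs: %g cmH2O/(L/s)\n", x$rrs))
  if (x$bilinear) {
    cat(sprintf("  compliance: bilinear %g/%g mL/cmH2O, LIP %g cmH2O\n",
                x$c_below, x$c_above, x$lip))
  } else {
    cat(sprintf("  compliance: linear %g mL/cmH2O\n", x$crs))
  }
  cat(if (is.null(x$aop)) "  airway closure: none\n"
      else sprintf("  airway opening pressure: %g cmH2O\n", x$aop))
  invisible(x)
}

#' Ventilator-circuit model
#'
#' The compressible volume of the ventilator tubing, characterised by its
#' compliance. While the airways are closed, all delivered gas compresses in
#' the circuit, which sets the first (steep) slope of the airway time-pressure
#' curve.
#'
#' @param ccirc Circuit compliance, mL/cmH2O (> 0). Default 2, a typical
#'   adult circuit.
#' @param rcirc Circuit resistance, cmH2O/(L/s) (>= 0). Currently lumped with
#'   airway resistance downstream of the Y piece and defaulting to 0.
#' @return An object of class `vent_circuit`.
#' @export
vent_circuit <- function(ccirc = 2, rcirc = 0) {
  check_number(ccirc, "ccirc", 0, strict = TRUE)
  check_number(rcirc, "rcirc", 0)
  structure(list(ccirc = ccirc, rcirc = rcirc), class = "vent_circuit")
}

#' Ventilator settings for a constant-flow breath
#'
#' Settings of a volume assist control breath delivered at constant
#' inspiratory flow, optionally followed by an end-inspiratory occlusion.
#'
#' @param insp_flow Constant inspiratory flow, L/min.
#' @param tidal_volume Delivered tidal volume, mL.
#' @param peep Set positive end-expiratory pressure, cmH2O.
#' @param rr Respiratory rate, breaths/min.
#' @param pause_s End-inspiratory occlusion duration, s. A plateau pressure
#'   (and hence the resistive pressure) requires at least 0.3 s.
#' @param exp_resistance Expiratory pathway resistance, cmH2O/(L/s), or
#'   `NULL` to default to the system's airway resistance at simulation time.
#' @return An object of class `vent_settings`.
#' @examples
#' vent_settings() # usual constant flow, 60 L/min
#' low_flow_settings() # quasi-static reference maneuver, 5 L/min
#' @export
vent_settings <- function(insp_flow = 60, tidal_volume = 420, peep = 5,
                          rr = 20, pause_s = 0.4, exp_resistance = NULL) {
  check_number(insp_flow, "insp_flow", 0, strict = TRUE)
  check_number(tidal_volume, "tidal_volume", 0, strict = TRUE)
  check_number(peep, "peep", 0)
  check_number(rr, "rr", 0, strict = TRUE)
  check_number(pause_s, "pause_s", 0)
  if (!is.null(exp_resistance)) check_number(exp_resistance, "exp_resistance", 0, strict = TRUE)
  structure(
    list(insp_flow = insp_flow, tidal_volume = tidal_volume, peep = peep,
         rr = rr, pause_s = pause_s, exp_resistance = exp_resistance),
    class = "vent_settings"
  )
}

#' @rdname vent_settings
#' @export
low_flow_settings <- function(insp_flow = 5, tidal_volume = 420, peep = 5,
                              rr = 5, pause_s = 0, exp_resistance = NULL) {
  vent_settings(insp_flow = insp_flow, tidal_volume = tidal_volume,
                peep = peep, rr = rr, pause_s = pause_s,
                exp_resistance = exp_resistance)
}

#' Simulation options
#'
#' @param fs Output sampling rate, Hz. Default 100, a realistic ventilator
#'   waveform rate.
#' @param noise_sd Standard deviation of additive Gaussian pressure-sensor
#'   noise, cmH2O, applied to the airway pressure only.
#' @param seed Integer seed for the noise generator, or `NULL` to use the
#'   current RNG state.
#' @param integrator_step Fixed integrator step, s. Must not exceed `1/fs`.
#' @param n_cycles Number of cycles simulated before the reported breath, so
#'   that the returned cycle is (close to) a steady state even when
#'   expiration is incomplete.
#' @param lead_s Length of end-expiratory tail from the preceding cycle
#'   included before the insufflation, s (clamped to the available
#'   expiration).
#' @param keep_state Keep the alveolar-volume state trace as attribute
#'   `state` of the returned waveform (used by conservation checks).
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(fs = 100, noise_sd = 0, seed = NULL,
                        integrator_step = 1e-3, n_cycles = 3, lead_s = 0.3,
                        keep_state = FALSE) {
  check_number(fs, "fs", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (!is.null(seed)) check_number(seed, "seed", -Inf)
  check_number(integrator_step, "integrator_step", 0, strict = TRUE)
  if (integrator_step > 1 / fs + 1e-12) {
    abort("`integrator_step` must not exceed the sampling interval 1/fs.")
  }
  check_number(n_cycles, "n_cycles", 1)
  check_number(lead_s, "lead_s", 0)
  structure(
    list(fs = fs, noise_sd = noise_sd, seed = seed,
         integrator_step = integrator_step, n_cycles = as.integer(n_cycles),
         lead_s = lead_s, keep_state = isTRUE(keep_state)),
    class = "sim_options"
  )
}
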