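new_breath_waveform <- function(t, flow, paw, volume, meta) {
  w <- tibble::tibble(t = t, flow = flow, paw = paw, volume = volume)
  attr(w, "meta") <- meta
  class(w) <- c("breath_waveform", class(w))
  w
}

#' @export
print.breath_waveform <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(
    "<breath_waveform> %d samples @ %g Hz | flow %g L/min | PEEP %g cmH2O%s\n",
    nrow(x), m$fs, m$flow_lpm, m$peep,
    if (!is.null(m$scenario)) paste0(" | scenario ", m$scenario) else ""
  ))
  NextMethod()
}

# dplyr/tidyr verbs drop unknown attributes; make sure meta survives slicing.
#' @export
`[.breath_waveform` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "meta") <- attr(x, "meta")
    class(out) <- unique(c("breath_waveform", class(out)))
  }
  out
}

waveform_meta <- function(w) attr(w, "meta")

#' Simulate one passive constant-flow ventilator breath
#'
#' Integrates the equation of motion of a passive single-compartment
#' respiratory system, `Paw = PEEPtot + Rrs * Flow + Ers * Volume`, coupled to
#' the compressible volume of the ventilator circuit, over full ventilatory
#' cycles, and returns the last cycle as a sampled waveform. When the system
#' has an airway opening pressure (AOP) above the set PEEP the breath starts
#' with a closed airway: delivered gas first compresses in the circuit, the
#' airway pressure rising at `insp_flow / ccirc`, until it reaches the AOP and
#' the airway snaps open. During expiration the lung empties passively toward
#' set PEEP and the airway re-closes (trapping gas at an alveolar pressure
#' equal to the AOP) once its recoil falls to the AOP.
#'
#' The returned waveform covers a short end-expiratory lead-in from the
#' preceding cycle, the insufflation, the end-inspiratory occlusion
#' (`pause_s`), and the expiration. Gaussian sensor noise (if any) is added to
#' the airway pressure only, after integration, under `opts$seed`.
#'
#' @param system A [respiratory_system()].
#' @param circuit A [vent_circuit()].
#' @param settings A [vent_settings()] (or [low_flow_settings()]).
#' @param opts A [sim_options()].
#' @return A `breath_waveform` tibble with columns `t` (s), `flow` (L/s,
#'   inspiratory positive), `paw` (cmH2O) and `volume` (mL, cumulative
#'   trapezoidal integral of `flow`), and a `meta` attribute carrying the
#'   provenance (sampling rate, settings, system, circuit).
#' @examples
#' sc <- bench_scenario("aop10")
#' w <- simulate_breath(sc$system, sc$circuit, vent_settings(peep = 5))
#' pcond_method(w)
#' @export
simulate_breath <- function(system, circuit = vent_circuit(),
                            settings = vent_settings(),
                            opts = sim_options()) {
  stopifnot(inherits(system, "respiratory_system"),
            inherits(circuit, "vent_circuit"),
            inherits(settings, "vent_settings"),
            inherits(opts, "sim_options"))

  q_lps <- settings$insp_flow / 60
  t_insp <- settings$tidal_volume / (q_lps * 1000)
  cycle_s <- 60 / settings$rr
  if (t_insp + settings$pause_s >= cycle_s) {
    abort(sprintf(
      paste0("Tidal volume unreachable before the inspiratory window ends: ",
             "insufflation (%.2f s) plus occlusion (%.2f s) exceeds the ",
             "cycle (%.2f s at rr = %g/min). Lower `tidal_volume` or ",
             "`pause_s`, or raise `insp_flow` or lower `rr`."),
      t_insp, settings$pause_s, cycle_s, settings$rr
    ))
  }
  r_exp <- settings$exp_resistance %||% system$rrs

  raw <- sim_core(
    rrs = system$rrs, bilinear = system$bilinear,
    c_below = system$c_below, c_above = system$c_above, lip = system$lip,
    has_aop = !is.null(system$aop), aop = system$aop %||% 0,
    ccirc = circuit$ccirc, q_insp = q_lps, vt = settings$tidal_volume,
    peep = settings$peep, pause_s = settings$pause_s, cycle_s = cycle_s,
    r_exp = r_exp, dt = opts$integrator_step, n_cycles = opts$n_cycles,
    fs = opts$fs
  )

  # window: end-expiratory tail of the penultimate cycle + the whole last cycle
  last <- max(raw$cycle)
  exp_dur <- cycle_s - t_insp - settings$pause_s
  lead <- min(opts$lead_s, exp_dur)
  t_start <- (last - 1) * cycle_s - lead
  keep <- raw$t >= t_start - 1e-9
  if (last == 1) keep <- rep(TRUE, length(raw$t)) # single cycle: no lead

  t <- raw$t[keep]
  t <- round((t - t[1]) * opts$fs) / opts$fs # re-zeroed exact uniform grid
  flow <- raw$flow[keep]
  paw <- raw$paw[keep]

  if (opts$noise_sd > 0) {
    noise <- if (is.null(opts$seed)) {
      rnorm(length(paw), 0, opts$noise_sd)
    } else {
      withr::with_seed(opts$seed, rnorm(length(paw), 0, opts$noise_sd))
    }
    paw <- paw + noise
  }

  meta <- list(
    fs = opts$fs, peep = settings$peep, flow_lpm = settings$insp_flow,
    tidal_volume = settings$tidal_volume, rr = settings$rr,
    pause_s = settings$pause_s, noise_sd = opts$noise_sd,
    seed = opts$seed, scenario = NULL,
    system = system, circuit = circuit, settings = settings
  )
  w <- new_breath_waveform(t, flow, paw, flow_to_volume(t, flow), meta)
  if (opts$keep_state) {
    attr(w, "state") <- tibble::tibble(
      t = t, paw_clean = raw$paw[keep],
      lung_volume = raw$valv[keep] - raw$valv[keep][1]
    )
  }
  w
}

#' Simulate the standard low-flow reference maneuver
#'
#' Same physics as [simulate_breath()] at a quasi-static inspiratory flow
#' (default 5 L/min, respiratory rate 5/min). With airway closure and PEEP
#' below the AOP the time-pressure curve shows two slopes: a first steep one
#' set by the circuit compliance while the airway is closed, breaking at
#' approximately `aop + rrs * flow` once it opens.
#'
#' @inheritParams simulate_breath
#' @param settings A [low_flow_settings()].
#' @return A `breath_waveform` tibble; see [simulate_breath()].
#' @export
simulate_low_flow_maneuver <- function(system, circuit = vent_circuit(),
                                       settings = low_flow_settings(),
                                       opts = sim_options()) {
  if (settings$insp_flow > 10) {
    warn(sprintf(
      "Low-flow maneuver requested at %g L/min; the reference method assumes a quasi-static flow (about 5 L/min).",
      settings$insp_flow
    ))
  }
  simulate_breath(system, circuit, settings, opts)
}

#' Closed-form constant-flow insufflation of a linear system
#'
#' Analytic solution of the equation of motion for a linear, closure-free
#' system with no circuit compliance: during insufflation
#' `paw(t) = peep + rrs * flow + flow * t * 1000 / crs`, exact to machine
#' precision. Serves as an independent oracle for the numerical simulator.
#'
#' @inheritParams simulate_breath
#' @param t_grid Times (s) within the insufflation, `0 <= t <= Vt/flow`.
#' @return A `breath_waveform` tibble covering the insufflation only.
#' @export
closed_form_linear <- function(system, settings = vent_settings(), t_grid) {
  stopifnot(inherits(system, "respiratory_system"),
            inherits(settings, "vent_settings"))
  if (system$bilinear) abort("closed_form_linear() requires a linear compliance.")
  if (!is.null(system$aop)) abort("closed_form_linear() requires a system without airway closure.")
  q_lps <- settings$insp_flow / 60
  t_insp <- settings$tidal_volume / (q_lps * 1000)
  if (any(t_grid < 0 | t_grid > t_insp + 1e-9)) {
    abort(sprintf("`t_grid` must lie within the insufflation [0, %.4f s].", t_insp))
  }
  volume <- q_lps * 1000 * t_grid
  paw <- settings$peep + system$rrs * q_lps + volume / system$crs
  fs <- if (length(t_grid) > 1) 1 / mean(diff(t_grid)) else NA_real_
  meta <- list(fs = fs, peep = settings$peep, flow_lpm = settings$insp_flow,
               tidal_volume = settings$tidal_volume, rr = settings$rr,
               pause_s = 0, noise_sd = 0, seed = NULL,
               scenario = "closed_form", system = system,
               circuit = NULL, settings = settings)
  new_breath_waveform(t_grid, rep(q_lps, length(t_grid)), paw, volume, meta)
}

#' Coerce a data frame to a breath waveform
#'
#' For waveforms from external sources: requires columns `t`, `flow`
#' (L/s) and `paw`; `volume` (mL) is recomputed from the flow trace when
#' absent.
#'
#' @param data A data frame with columns `t` (s, uniform grid), `flow` (L/s)
#'   and `paw` (cmH2O), optionally `volume` (mL).
#' @param fs Sampling rate, Hz; inferred from `t` when `NULL`.
#' @param peep Set PEEP, cmH2O (stored in metadata, used as the default
#'   reference by the detection methods).
#' @param flow_lpm Set inspiratory flow, L/min (metadata only).
#' @return A `breath_waveform` tibble.
#' @export
as_breath_waveform <- function(data, fs = NULL, peep = NULL, flow_lpm = NULL) {
  req <- c("t", "flow", "paw")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 2) abort("A waveform needs at least 2 samples.")
  dt <- diff(data$t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) abort("`t` must be a uniform grid.")
  vol <- if ("volume" %in% names(data)) data$volume else flow_to_volume(data$t, data$flow)
  meta <- list(fs = fs %||% (1 / stats::median(dt)), peep = peep,
               flow_lpm = flow_lpm, noise_sd = NA, scenario = NULL)
  new_breath_waveform(data$t, data$flow, data$paw, vol, meta)
}
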