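#' Bench scenarios
#'
#' The three mechanical-bench models used to validate the conductive-pressure
#' method, shipped as YAML fixtures: `"aop10"` (airway closure at 10 cmH2O,
#' linear compliance 40 mL/cmH2O), `"control1"` (linear compliance, no
#' closure) and `"control2"` (bilinear compliance 20/40 mL/cmH2O with a lower
#' inflection point at 10 cmH2O, no closure). Airway resistance is 10
#' cmH2O/(L/s) in all three.
#'
#' @param name One of `"aop10"`, `"control1"`, `"control2"`, or a path to a
#'   scenario YAML file.
#' @return A list with elements `name`, `system` (a [respiratory_system()])
#'   and `circuit` (a [vent_circuit()]).
#' @examples
#' bench_scenario("control2")$system
#' @export
bench_scenario <- function(name) {
  shipped <- c("aop10", "control1", "control2")
  path <- if (name %in% shipped) {
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "pcond", mustWork = TRUE)
  } else {
    name
  }
  read_scenario(path)
}

#' @rdname bench_scenario
#' @param path Path to a scenario YAML file with fields `name`,
#'   `system` (`rrs`, `compliance` as either `linear: Crs` or
#'   `bilinear: {c_below, c_above, lip}`, optional `aop`) and `circuit`
#'   (`ccirc`, optional `rcirc`).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scenario file not found: %s", path))
  y <- yaml::read_yaml(path)
  for (f in c("system", "circuit")) {
    if (is.null(y[[f]])) abort(sprintf("Scenario file %s lacks a `%s` block.", path, f))
  }
  comp <- y$system$compliance
  if (is.null(comp)) abort("Scenario system lacks a `compliance` block.")
  system <- if (!is.null(comp$linear)) {
    respiratory_system(rrs = y$system$rrs, crs = comp$linear, aop = y$system$aop)
  } else if (!is.null(comp$bilinear)) {
    respiratory_system(rrs = y$system$rrs, c_below = comp$bilinear$c_below,
                       c_above = comp$bilinear$c_above, lip = comp$bilinear$lip,
                       aop = y$system$aop)
  } else {
    abort("Scenario compliance must be `linear` or `bilinear`.")
  }
  circuit <- vent_circuit(ccirc = y$circuit$ccirc,
                          rcirc = y$circuit$rcirc %||% 0)
  list(name = y$name %||% basename(path), system = system, circuit = circuit)
}

#' Simulate a bench scenario
#'
#' Convenience wrapper: simulate one breath of a named bench scenario at a
#' given PEEP, either at the usual constant flow (60 L/min, with
#' end-inspiratory occlusion) or as the low-flow reference maneuver.
#'
#' @param scenario A scenario name/path (see [bench_scenario()]) or a
#'   scenario list.
#' @param peep Set PEEP, cmH2O.
#' @param low_flow Simulate the 5 L/min reference maneuver instead of the
#'   60 L/min breath.
#' @param settings Optional [vent_settings()] overriding the defaults (its
#'   `peep` is replaced by `peep`).
#' @param opts A [sim_options()].
#' @return A `breath_waveform` tibble.
#' @examples
#' w <- simulate_scenario("aop10", peep = 5)
#' standard_method(simulate_scenario("aop10", peep = 5, low_flow = TRUE))
#' @export
simulate_scenario <- function(scenario, peep = 5, low_flow = FALSE,
                              settings = NULL, opts = sim_options()) {
  sc <- if (is.character(scenario)) bench_scenario(scenario) else scenario
  if (is.null(settings)) {
    settings <- if (low_flow) low_flow_settings(peep = peep)
                else vent_settings(peep = peep)
  } else {
    settings$peep <- peep
  }
  w <- if (low_flow) simulate_low_flow_maneuver(sc$system, sc$circuit, settings, opts)
       else simulate_breath(sc$system, sc$circuit, settings, opts)
  m <- attr(w, "meta")
  m$scenario <- sc$name
  attr(w, "meta") <- m
  w
}
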