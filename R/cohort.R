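#' Synthetic validation-cohort specification
#'
#' Parameters of the synthetic cohort that emulates the clinical validation
#' population: passive constant-flow breaths, about 26% prevalence of airway
#' closure, and closure AOPs lognormally distributed with median 10 cmH2O and
#' an interquartile range of roughly 9-13 cmH2O, truncated above
#' `peep + 1`. Per-case mechanics are drawn uniformly from plausible passive
#' ARDS ranges.
#'
#' @param n Number of cases.
#' @param prevalence Probability of airway closure per case. Default 0.26.
#' @param aop_meanlog,aop_sdlog Lognormal parameters of the AOP given
#'   closure. Defaults keep the median exactly 10 cmH2O and match the
#'   9-13 cmH2O interquartile width on the log scale.
#' @param rrs_range Uniform range of airway resistance, cmH2O/(L/s).
#' @param crs_range Uniform range of compliance, mL/cmH2O.
#' @param peep Set PEEP of both maneuvers, cmH2O. Default 5.
#' @param noise_sd Pressure sensor noise, cmH2O. Default 0.3.
#' @param flow_lpm,lowflow_lpm Inspiratory flows of the two maneuvers, L/min.
#' @param tidal_volume Delivered tidal volume, mL.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence = 0.26, aop_meanlog = log(10),
                        aop_sdlog = (log(13) - log(9)) / (2 * stats::qnorm(0.75)),
                        rrs_range = c(5, 20), crs_range = c(20, 60), peep = 5,
                        noise_sd = 0.3, flow_lpm = 60, lowflow_lpm = 5,
                        tidal_volume = 420, seed = 1) {
  check_number(n, "n", 1)
  check_number(prevalence, "prevalence", 0)
  if (prevalence > 1) abort("`prevalence` must lie in [0, 1].")
  stopifnot(length(rrs_range) == 2, length(crs_range) == 2)
  if (any(rrs_range <= 0) || any(crs_range <= 0)) abort("Mechanics ranges must be positive.")
  check_number(noise_sd, "noise_sd", 0)
  check_number(seed, "seed")
  structure(
    list(n = as.integer(n), prevalence = prevalence,
         aop_meanlog = aop_meanlog, aop_sdlog = aop_sdlog,
         rrs_range = sort(rrs_range), crs_range = sort(crs_range),
         peep = peep, noise_sd = noise_sd, flow_lpm = flow_lpm,
         lowflow_lpm = lowflow_lpm, tidal_volume = tidal_volume,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# AOP draw truncated to > lo, resampled with a retry cap.
draw_aop <- function(n, meanlog, sdlog, lo, max_tries = 1000) {
  out <- rlnorm(n, meanlog, sdlog)
  tries <- 0
  while (any(bad <- out <= lo)) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort(sprintf(
        "AOP distribution keeps producing values at or below PEEP + 1 (= %g cmH2O); check `aop_meanlog`/`aop_sdlog`.", lo
      ))
    }
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  out
}

#' Generate a synthetic validation cohort
#'
#' Draws per-case mechanics and closure status from a [cohort_spec()] and
#' simulates, for each case, one breath at usual constant flow (with
#' end-inspiratory occlusion) and one low-flow reference maneuver, both at
#' the spec's PEEP. Fully reproducible from `spec$seed`; the truth table is
#' identical whether or not waveforms are generated.
#'
#' @param spec A [cohort_spec()].
#' @param waveforms Also simulate the two waveforms per case (list-columns
#'   `waveform_60` and `waveform_5`). Set `FALSE` for a truth-only table,
#'   e.g. to check the generator's marginals cheaply.
#' @return A tibble with one row per case: `case_id`, `closure`, `aop`
#'   (`NA` without closure), `rrs`, `crs`, and optionally the two waveform
#'   list-columns.
#' @examples
#' truth <- generate_cohort(cohort_spec(n = 50, seed = 7), waveforms = FALSE)
#' mean(truth$closure)
#' @export
generate_cohort <- function(spec, waveforms = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- withr::with_seed(spec$seed, {
    n <- spec$n
    closure <- runif(n) < spec$prevalence
    aop <- rep(NA_real_, n)
    if (any(closure)) {
      aop[closure] <- draw_aop(sum(closure), spec$aop_meanlog, spec$aop_sdlog,
                               lo = spec$peep + 1)
    }
    tibble::tibble(
      case_id = sprintf("case_%04d", seq_len(n)),
      closure = closure, aop = aop,
      rrs = runif(n, spec$rrs_range[1], spec$rrs_range[2]),
      crs = runif(n, spec$crs_range[1], spec$crs_range[2]),
      seed_60 = sample.int(.Machine$integer.max, n),
      seed_5 = sample.int(.Machine$integer.max, n)
    )
  })
  if (!waveforms) {
    return(dplyr::select(truth, -"seed_60", -"seed_5"))
  }
  sim_case <- function(rrs, crs, aop, s60, s5) {
    sys <- respiratory_system(rrs = rrs, crs = crs,
                              aop = if (is.na(aop)) NULL else aop)
    list(
      w60 = simulate_breath(
        sys, settings = vent_settings(insp_flow = spec$flow_lpm,
                                      tidal_volume = spec$tidal_volume,
                                      peep = spec$peep),
        opts = sim_options(noise_sd = spec$noise_sd, seed = s60)
      ),
      w5 = simulate_low_flow_maneuver(
        sys, settings = low_flow_settings(insp_flow = spec$lowflow_lpm,
                                          tidal_volume = spec$tidal_volume,
                                          peep = spec$peep),
        opts = sim_options(noise_sd = spec$noise_sd, seed = s5)
      )
    )
  }
  sims <- purrr::pmap(
    list(truth$rrs, truth$crs, truth$aop, truth$seed_60, truth$seed_5),
    sim_case
  )
  truth$waveform_60 <- purrr::map(sims, "w60")
  truth$waveform_5 <- purrr::map(sims, "w5")
  dplyr::select(truth, -"seed_60", -"seed_5")
}

#' Run a detector over a cohort
#'
#' Applies [pcond_method()] to each case's constant-flow waveform (or
#' [standard_method()] to the low-flow one) and stacks the results.
#'
#' @param cohort A cohort tibble from [generate_cohort()] with waveforms.
#' @param method `"pcond"` or `"standard"`.
#' @param cfg A [detection_config()].
#' @return A tibble with `case_id` and the [pcond_method()] /
#'   [standard_method()] result columns.
#' @export
cohort_detect <- function(cohort, method = c("pcond", "standard"),
                          cfg = detection_config()) {
  method <- match.arg(method)
  col <- if (method == "pcond") "waveform_60" else "waveform_5"
  if (!col %in% names(cohort)) {
    abort(sprintf("Cohort lacks the `%s` waveform column; regenerate with waveforms = TRUE.", col))
  }
  fun <- if (method == "pcond") pcond_method else standard_method
  res <- purrr::map(cohort[[col]], fun, cfg = cfg)
  dplyr::bind_cols(
    tibble::tibble(case_id = cohort$case_id),
    dplyr::bind_rows(lapply(res, tibble::as_tibble))
  )
}
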