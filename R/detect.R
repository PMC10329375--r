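#' Detector configuration
#'
#' All constants of the airway-closure detector. Defaults implement the
#' published decision rule (closure when `Pcond - Pres > 1` cmH2O, plateau
#' after at least 0.3 s of occlusion) plus the numerical choices of the
#' automated slope-break fit.
#'
#' @param closure_threshold Closure decision threshold on `Pcond - Pres`,
#'   cmH2O (> 0). Default 1.
#' @param onset_flow_threshold Flow defining the start of insufflation,
#'   L/min. Default 2.
#' @param break_window_s Window after onset searched for the early slope
#'   break at usual constant flow, s. Default 0.2: long enough to cover the
#'   circuit-charging phase and the opening transient for plausible AOPs, yet
#'   ending before the pressure-volume nonlinearities (e.g. a lower
#'   inflection point) that bend the curve later in the insufflation. The
#'   low-flow method always searches the full insufflation.
#' @param plateau_window_s Window averaged at the end of the occlusion for
#'   the plateau pressure, s. Default 0.1.
#' @param min_pause_s Minimum occlusion length for a valid plateau, s.
#'   At least 0.3.
#' @param slope_ratio_min Minimum `slope1/slope2` for a qualifying slope
#'   break in the low-flow method. Default 5: a circuit-compliance first
#'   slope is an order of magnitude steeper than the elastic slope
#'   (about `Crs/Ccirc`), while a lower inflection point of a bilinear
#'   compliance only halves the slope, so 5 separates the two cleanly.
#' @param sse_ratio_min Minimum ratio of one-segment to two-segment residual
#'   sum of squares for a qualifying break. Default 5.
#' @param occlusion_flow_threshold Absolute flow below which a sample counts
#'   as occluded, L/min. Default 0.5.
#' @param intrinsic_peep_flow_threshold End-expiratory flow above which
#'   intrinsic PEEP is flagged, L/min. Default 2.
#' @param report_rounding Resolution of the reported AOP, cmH2O. Default 1,
#'   matching clinical reporting; raw values are always retained.
#' @param smooth Apply a 3-sample moving average to the pressure before
#'   fitting. Off by default (unnecessary at sensor noise below about 0.3
#'   cmH2O).
#' @param actual_flow_correction Rescale `Pres` to the flow recorded at the
#'   break instant instead of the end-insufflation flow. A no-op at constant
#'   flow; off by default.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(closure_threshold = 1, onset_flow_threshold = 2,
                             break_window_s = 0.2, plateau_window_s = 0.1,
                             min_pause_s = 0.3, slope_ratio_min = 5,
                             sse_ratio_min = 5, occlusion_flow_threshold = 0.5,
                             intrinsic_peep_flow_threshold = 2,
                             report_rounding = 1, smooth = FALSE,
                             actual_flow_correction = FALSE) {
  check_number(closure_threshold, "closure_threshold", 0, strict = TRUE)
  check_number(onset_flow_threshold, "onset_flow_threshold", 0, strict = TRUE)
  check_number(break_window_s, "break_window_s", 0, strict = TRUE)
  check_number(plateau_window_s, "plateau_window_s", 0, strict = TRUE)
  check_number(min_pause_s, "min_pause_s", 0.3)
  check_number(slope_ratio_min, "slope_ratio_min", 1, strict = TRUE)
  check_number(sse_ratio_min, "sse_ratio_min", 1, strict = TRUE)
  check_number(occlusion_flow_threshold, "occlusion_flow_threshold", 0, strict = TRUE)
  check_number(intrinsic_peep_flow_threshold, "intrinsic_peep_flow_threshold", 0, strict = TRUE)
  check_number(report_rounding, "report_rounding", 0, strict = TRUE)
  structure(
    list(closure_threshold = closure_threshold,
         onset_flow_threshold = onset_flow_threshold,
         break_window_s = break_window_s,
         plateau_window_s = plateau_window_s, min_pause_s = min_pause_s,
         slope_ratio_min = slope_ratio_min, sse_ratio_min = sse_ratio_min,
         occlusion_flow_threshold = occlusion_flow_threshold,
         intrinsic_peep_flow_threshold = intrinsic_peep_flow_threshold,
         report_rounding = report_rounding, smooth = isTRUE(smooth),
         actual_flow_correction = isTRUE(actual_flow_correction)),
    class = "detection_config"
  )
}

maybe_smooth <- function(paw, cfg) {
  if (!cfg$smooth || length(paw) < 3) return(paw)
  sm <- stats::filter(paw, rep(1 / 3, 3), sides = 2)
  sm[1] <- paw[1]
  sm[length(paw)] <- paw[length(paw)]
  as.numeric(sm)
}

#' Locate the start of insufflation
#'
#' First sample where flow exceeds `onset_flow_threshold` and stays above it
#' for at least 3 samples.
#'
#' @param w A `breath_waveform`.
#' @param cfg A [detection_config()].
#' @return Integer sample index.
#' @export
detect_onset <- function(w, cfg = detection_config()) {
  thr <- cfg$onset_flow_threshold / 60
  above <- w$flow > thr
  n <- length(above)
  if (n >= 3) {
    run3 <- above[1:(n - 2)] & above[2:(n - 1)] & above[3:n]
    idx <- which(run3)
  } else {
    idx <- integer(0)
  }
  if (length(idx) == 0) abort("no insufflation found")
  idx[1]
}

#' End of insufflation (first occluded/expiratory sample after onset)
#' @noRd
insufflation_end <- function(w, onset, cfg) {
  thr <- cfg$occlusion_flow_threshold / 60
  below <- which(w$flow[(onset + 1):nrow(w)] < thr)
  if (length(below) == 0) return(nrow(w))
  onset + below[1] - 1 # last insufflation sample
}

#' Two-segment piecewise-linear slope-break fit
#'
#' Fits a continuous two-segment piecewise-linear model of airway pressure
#' versus time over `[onset, onset + window_s]` by exhaustive search of the
#' breakpoint on the sample grid, minimizing the total sum of squared
#' residuals (earlier breakpoint wins ties). Returns the fitted pressure at
#' the breakpoint, both slopes, and the ratio of the one-segment to the
#' two-segment residual sum of squares (a quality measure: about 1 for a
#' straight line, large when a genuine break exists).
#'
#' @param w A `breath_waveform`.
#' @param onset Sample index of the start of insufflation
#'   (see [detect_onset()]).
#' @param window_s Length of the fitted window, s.
#' @param cfg A [detection_config()].
#' @return A one-row tibble: `t_break`, `p_break`, `slope1`, `slope2`,
#'   `sse_ratio`.
#' @export
fit_slope_break <- function(w, onset, window_s, cfg = detection_config()) {
  fs <- waveform_meta(w)$fs %||% (1 / mean(diff(w$t)))
  i_end <- min(nrow(w), onset + as.integer(round(window_s * fs)))
  idx <- onset:i_end
  if (length(idx) < 6) abort("slope-break window must contain at least 6 samples")
  t <- w$t[idx]
  p <- maybe_smooth(w$paw[idx], cfg)
  n <- length(t)

  # degenerate: (near-)constant pressure
  if (stats::var(p) < 1e-16) {
    return(tibble::tibble(t_break = t[1], p_break = mean(p), slope1 = 0,
                          slope2 = 0, sse_ratio = 1))
  }

  sse1 <- sum(stats::lm.fit(cbind(1, t), p)$residuals^2)

  cand <- 3:(n - 2) # at least 3 samples in each segment (break shared)
  best <- NULL
  best_sse <- Inf
  for (j in cand) {
    tb <- t[j]
    X <- cbind(1, pmin(t - tb, 0), pmax(t - tb, 0))
    fit <- stats::lm.fit(X, p)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 1e-12) { # strict improvement: earlier tie wins
      best_sse <- sse
      best <- list(tb = tb, coef = fit$coefficients)
    }
  }
  sse_ratio <- if (sse1 <= 1e-9) 1 else sse1 / max(best_sse, sse1 * 1e-9)
  tibble::tibble(
    t_break = best$tb, p_break = unname(best$coef[1]),
    slope1 = unname(best$coef[2]), slope2 = unname(best$coef[3]),
    sse_ratio = sse_ratio
  )
}

#' Peak and plateau pressure
#'
#' Peak is the maximum airway pressure during insufflation; plateau is the
#' mean pressure over the final `plateau_window_s` of an end-inspiratory
#' occlusion that must last at least `min_pause_s` (0.3 s by default).
#' Their difference is the resistive pressure `Pres`.
#'
#' @inheritParams detect_onset
#' @return A one-row tibble: `peak`, `plateau`, `p_res`.
#' @export
measure_peak_plateau <- function(w, cfg = detection_config()) {
  onset <- detect_onset(w, cfg)
  i_end <- insufflation_end(w, onset, cfg)
  # the first occluded sample still holds the end-insufflation pressure
  # (the occlusion decay starts after it), so include it in the peak search
  peak <- max(w$paw[onset:min(i_end + 1L, nrow(w))])

  thr <- cfg$occlusion_flow_threshold / 60
  i <- i_end + 1
  n <- nrow(w)
  occ <- integer(0)
  while (i <= n && abs(w$flow[i]) < thr) {
    occ <- c(occ, i)
    i <- i + 1
  }
  fs <- waveform_meta(w)$fs %||% (1 / mean(diff(w$t)))
  dur <- length(occ) / fs
  if (dur < cfg$min_pause_s) {
    abort(sprintf(
      "occlusion too short: %.2f s of zero flow after insufflation, need at least %.2f s for a plateau",
      dur, cfg$min_pause_s
    ))
  }
  n_pl <- max(1L, as.integer(round(cfg$plateau_window_s * fs)))
  plateau <- mean(w$paw[utils::tail(occ, n_pl)])
  tibble::tibble(peak = peak, plateau = plateau, p_res = peak - plateau)
}

#' Flag intrinsic PEEP from end-expiratory flow
#'
#' `TRUE` when the absolute flow at the last sample before insufflation
#' exceeds `intrinsic_peep_flow_threshold` (default 2 L/min), i.e. expiration
#' was still ongoing when the next breath started. Results obtained under
#' intrinsic PEEP are unreliable because the set PEEP underestimates total
#' PEEP.
#'
#' @inheritParams detect_onset
#' @return Logical scalar.
#' @export
detect_intrinsic_peep <- function(w, cfg = detection_config()) {
  onset <- tryCatch(detect_onset(w, cfg), error = function(e) NA_integer_)
  if (is.na(onset) || onset <= 1) return(FALSE)
  abs(w$flow[onset - 1]) * 60 > cfg$intrinsic_peep_flow_threshold
}

new_aop_result <- function(row, cfg) {
  out <- tibble::as_tibble(row)
  attr(out, "config") <- cfg
  class(out) <- c("aop_result", class(out))
  out
}

#' @export
print.aop_result <- function(x, ...) {
  cat(sprintf("<aop_result: %s method>\n", x$method))
  if (isTRUE(x$closure_detected)) {
    cat(sprintf("  airway closure detected: AOP %g cmH2O (raw %.2f)\n",
                x$aop, x$aop_raw))
  } else {
    cat("  no airway closure detected (no AOP above PEEP)\n")
  }
  if (isTRUE(x$intrinsic_peep)) {
    cat("  WARNING: intrinsic PEEP flagged; result unreliable\n")
  }
  NextMethod()
}

#' Conductive-pressure (Pcond) method
#'
#' Detects airway closure and measures the airway opening pressure from a
#' single passive breath at usual constant flow with an end-inspiratory
#' occlusion. The conductive pressure is the fitted pressure of the abrupt
#' early-insufflation slope break minus the set PEEP; the resistive pressure
#' is peak minus plateau. Closure is called when
#' `Pcond - Pres > closure_threshold` (1 cmH2O), and then
#' `AOP = PEEP + (Pcond - Pres)`.
#'
#' @param w A `breath_waveform` recorded (or simulated) at usual constant
#'   flow with an occlusion of at least 0.3 s.
#' @param set_peep Set PEEP, cmH2O; defaults to the waveform metadata.
#' @param cfg A [detection_config()].
#' @return A one-row `aop_result` tibble: `method`, `closure_detected`,
#'   `aop` (reported, `NA` when no closure), `aop_raw`, `p_cond`, `p_res`,
#'   `p_break`, `peak`, `plateau`, `set_peep`, `intrinsic_peep`, `slope1`,
#'   `slope2`, `sse_ratio`. `aop_raw` equals `set_peep + (p_cond - p_res)`
#'   exactly; `aop` is rounded to `report_rounding`.
#' @examples
#' w <- simulate_scenario("aop10", peep = 5)
#' pcond_method(w)
#' @export
pcond_method <- function(w, set_peep = NULL, cfg = detection_config()) {
  set_peep <- set_peep %||% waveform_meta(w)$peep
  if (is.null(set_peep)) abort("`set_peep` must be given when the waveform carries no PEEP metadata.")
  ipeep <- detect_intrinsic_peep(w, cfg)
  onset <- detect_onset(w, cfg)
  i_end <- insufflation_end(w, onset, cfg)
  fs <- waveform_meta(w)$fs %||% (1 / mean(diff(w$t)))
  window_s <- min(cfg$break_window_s, (i_end - onset) / fs)
  br <- fit_slope_break(w, onset, window_s, cfg)
  pp <- measure_peak_plateau(w, cfg)

  p_res <- pp$p_res
  if (cfg$actual_flow_correction) {
    i_break <- which.min(abs(w$t - br$t_break))
    f_end <- w$flow[i_end]
    if (is.finite(f_end) && f_end > 0) p_res <- p_res * w$flow[i_break] / f_end
  }
  p_cond <- br$p_break - set_peep
  excess <- p_cond - p_res
  detected <- excess > cfg$closure_threshold
  aop_raw <- if (detected) set_peep + excess else NA_real_
  new_aop_result(
    list(method = "pcond", closure_detected = detected,
         aop = if (detected) round_to_resolution(aop_raw, cfg$report_rounding) else NA_real_,
         aop_raw = aop_raw, p_cond = p_cond, p_res = p_res,
         p_break = br$p_break, peak = pp$peak, plateau = pp$plateau,
         set_peep = set_peep, intrinsic_peep = ipeep,
         slope1 = br$slope1, slope2 = br$slope2, sse_ratio = br$sse_ratio),
    cfg
  )
}

#' Standard low-flow reference method
#'
#' Detects airway closure on a low-flow (about 5 L/min) insufflation as an
#' abrupt slope change on the time-pressure curve: the two-segment fit over
#' the whole insufflation must improve the one-segment fit by at least
#' `sse_ratio_min`, the first slope must exceed the second by at least
#' `slope_ratio_min`, and the break pressure must sit more than
#' `closure_threshold` above PEEP. The pressure at the qualifying break is
#' the AOP.
#'
#' @param w A low-flow `breath_waveform`.
#' @inheritParams pcond_method
#' @return A one-row `aop_result` tibble (see [pcond_method()]); `p_cond`,
#'   `p_res` and `plateau` are `NA` for this method.
#' @examples
#' w5 <- simulate_scenario("aop10", peep = 5, low_flow = TRUE)
#' standard_method(w5)
#' @export
standard_method <- function(w, set_peep = NULL, cfg = detection_config()) {
  set_peep <- set_peep %||% waveform_meta(w)$peep
  if (is.null(set_peep)) abort("`set_peep` must be given when the waveform carries no PEEP metadata.")
  ipeep <- detect_intrinsic_peep(w, cfg)
  onset <- detect_onset(w, cfg)
  i_end <- insufflation_end(w, onset, cfg)
  fs <- waveform_meta(w)$fs %||% (1 / mean(diff(w$t)))
  br <- fit_slope_break(w, onset, (i_end - onset) / fs, cfg)

  slope_ratio <- if (br$slope2 > 0) br$slope1 / br$slope2 else Inf
  detected <- br$sse_ratio >= cfg$sse_ratio_min &&
    slope_ratio >= cfg$slope_ratio_min &&
    (br$p_break - set_peep) > cfg$closure_threshold
  aop_raw <- if (detected) br$p_break else NA_real_
  new_aop_result(
    list(method = "standard", closure_detected = detected,
         aop = if (detected) round_to_resolution(aop_raw, cfg$report_rounding) else NA_real_,
         aop_raw = aop_raw, p_cond = NA_real_, p_res = NA_real_,
         p_break = br$p_break, peak = max(w$paw[onset:i_end]),
         plateau = NA_real_, set_peep = set_peep, intrinsic_peep = ipeep,
         slope1 = br$slope1, slope2 = br$slope2, sse_ratio = br$sse_ratio),
    cfg
  )
}
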