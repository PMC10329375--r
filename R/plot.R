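#' Plot a breath waveform
#'
#' Airway pressure and flow against time, one panel each.
#'
#' @param object A `breath_waveform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(simulate_scenario("aop10", peep = 5))
#' @export
autoplot.breath_waveform <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("t", "paw", "flow")],
    c("paw", "flow"), names_to = "signal", values_to = "value"
  )
  long$signal <- factor(long$signal, c("paw", "flow"),
                        c("airway pressure (cmH2O)", "flow (L/s)"))
  m <- waveform_meta(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = if (!is.null(m$scenario)) paste("scenario", m$scenario) else NULL,
      subtitle = sprintf("flow %g L/min, PEEP %g cmH2O", m$flow_lpm, m$peep)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' Plot a detection result over its waveform
#'
#' Pressure-time curve with the fitted slope break, peak and plateau
#' annotated; the visual counterpart of the conductive-pressure reading.
#'
#' @param w The `breath_waveform` the result was computed from.
#' @param result An `aop_result` from [pcond_method()] or
#'   [standard_method()].
#' @return A ggplot object.
#' @examples
#' w <- simulate_scenario("aop10", peep = 5)
#' plot_detection(w, pcond_method(w))
#' @export
plot_detection <- function(w, result) {
  stopifnot(inherits(result, "aop_result"))
  p <- ggplot2::ggplot(tibble::as_tibble(w),
                       ggplot2::aes(x = .data$t, y = .data$paw)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = result$set_peep, linetype = 3) +
    ggplot2::annotate("point", x = result_t_break(w, result),
                      y = result$p_break, colour = "red", size = 2) +
    ggplot2::labs(x = "time (s)", y = "airway pressure (cmH2O)",
                  subtitle = if (isTRUE(result$closure_detected)) {
                    sprintf("%s method: AOP %g cmH2O", result$method, result$aop)
                  } else {
                    sprintf("%s method: no AOP above PEEP", result$method)
                  }) +
    ggplot2::theme_minimal()
  if (is.finite(result$plateau)) {
    p <- p + ggplot2::geom_hline(yintercept = result$plateau, linetype = 2,
                                 colour = "grey40")
  }
  p
}

result_t_break <- function(w, result) {
  w$t[which.min(abs(w$paw - result$p_break))]
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and 95% limits of agreement.
#'
#' @param object An `agreement_report` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  d <- attr(object, "data")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "mean of methods (cmH2O)",
                  y = "difference, reference - comparator (cmH2O)",
                  subtitle = sprintf("bias %.2f, limits of agreement [%.2f, %.2f], n = %d",
                                     object$bias, object$loa_low,
                                     object$loa_high, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.agreement_report
#' @export
autoplot.detector_evaluation <- function(object, ...) {
  if (is.null(object$agreement)) {
    abort("No agreement analysis available (fewer than 2 shared positives).")
  }
  autoplot(object$agreement) +
    ggplot2::labs(y = "difference, truth - detector (cmH2O)")
}
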