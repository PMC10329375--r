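# Internal helpers shared across modules.

# Round half away from zero (printed clinical tables round 92.5 -> 93,
# base round() would give 92).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round to the nearest multiple of `resolution` (e.g. 1 cmH2O), half up.
round_to_resolution <- function(x, resolution = 1) {
  round_half_up(x / resolution) * resolution
}

check_number <- function(x, name, lower = -Inf, strict = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s (got %g).", name,
      if (strict) "greater than" else "at least", format(lower), x
    ))
  }
  invisible(x)
}

# Cumulative volume (mL) from a sampled flow trace (L/s) by trapezoidal
# integration, anchored at zero.
flow_to_volume <- function(t, flow) {
  1000 * pracma::cumtrapz(t, flow)[, 1]
}
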