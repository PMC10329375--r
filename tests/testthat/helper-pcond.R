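# Shared fixtures, all generated in code.

# A hand-built waveform on a uniform grid for direct detector tests.
make_waveform <- function(t, flow, paw, fs = NULL, peep = NULL, flow_lpm = NULL) {
  as_breath_waveform(tibble::tibble(t = t, flow = flow, paw = paw),
                     fs = fs, peep = peep, flow_lpm = flow_lpm)
}

# A square constant-flow insufflation starting at `t_on` with a piecewise
# linear pressure trace (the fitted model class of the slope-break fit).
piecewise_breath <- function(fs = 100, t_on = 0.2, dur = 0.4,
                             p0 = 5, slope1 = 500, slope2 = 12, t_knee = 0.03,
                             flow_lps = 1) {
  t <- seq(0, t_on + dur, by = 1 / fs)
  insp <- t >= t_on
  tt <- pmax(t - t_on, 0)
  paw <- p0 + ifelse(tt <= t_knee, slope1 * tt,
                     slope1 * t_knee + slope2 * (tt - t_knee))
  paw[!insp] <- p0
  make_waveform(t, ifelse(insp, flow_lps, 0), paw, fs = fs, peep = p0,
                flow_lpm = flow_lps * 60)
}

# Independent direct-scan oracle for the insufflation onset: first index
# opening a run of >= 3 samples above the threshold.
onset_oracle <- function(flow, thr_lpm = 2) {
  above <- flow > thr_lpm / 60
  for (i in seq_len(length(above) - 2)) {
    if (above[i] && above[i + 1] && above[i + 2]) return(i)
  }
  NA_integer_
}

bench_60 <- function(name, peep, ...) {
  simulate_scenario(name, peep = peep, low_flow = FALSE, ...)
}
bench_5 <- function(name, peep, ...) {
  simulate_scenario(name, peep = peep, low_flow = TRUE, ...)
}
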