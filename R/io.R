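#' Read and write waveform files
#'
#' Waveforms are stored as delimited text: comment lines prefixed `#` carry
#' `key=value` metadata (at least `fs`, `peep`, `flow_lpm`), followed by a
#' CSV table with columns `t_s`, `flow_lps`, `paw_cmh2o` and `volume_ml`.
#' Both LF and CRLF line endings are accepted. Round trips are lossless to 6
#' significant digits.
#'
#' @param w A `breath_waveform`.
#' @param path File path.
#' @return `read_waveform()` returns a `breath_waveform` tibble;
#'   `write_waveform()` returns `path` invisibly.
#' @examples
#' w <- simulate_scenario("control1", peep = 5)
#' f <- tempfile(fileext = ".csv")
#' write_waveform(w, f)
#' all.equal(read_waveform(f)$paw, w$paw, tolerance = 1e-6)
#' @export
write_waveform <- function(w, path) {
  m <- waveform_meta(w) %||% list()
  scalars <- list(
    fs = m$fs, peep = m$peep, flow_lpm = m$flow_lpm,
    tidal_volume = m$tidal_volume, rr = m$rr, pause_s = m$pause_s,
    noise_sd = m$noise_sd, seed = m$seed, scenario = m$scenario
  )
  scalars <- scalars[!vapply(scalars, is.null, logical(1))]
  header <- sprintf("#%s=%s", names(scalars),
                    vapply(scalars, function(v) format(v, digits = 10), character(1)))
  body <- sprintf("%.9g,%.9g,%.9g,%.9g", w$t, w$flow, w$paw, w$volume)
  writeLines(c(header, "t_s,flow_lps,paw_cmh2o,volume_ml", body), path)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines) # tolerate CRLF
  is_meta <- grepl("^#", lines)
  n_head <- match(FALSE, is_meta, nomatch = length(lines) + 1) - 1

  meta <- list()
  for (i in seq_len(n_head)) {
    kv <- sub("^#", "", lines[i])
    if (!grepl("=", kv, fixed = TRUE)) {
      abort(sprintf("Malformed metadata header at line %d of %s: `%s` (expected key=value).",
                    i, path, lines[i]))
    }
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (is.na(num)) trimws(val) else num
  }

  df <- tryCatch(
    read.csv(text = paste(lines[(n_head + 1):length(lines)], collapse = "\n")),
    error = function(e) abort(sprintf("Could not parse the data table of %s: %s", path, conditionMessage(e)))
  )
  required <- c("t_s", "flow_lps", "paw_cmh2o")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Missing column(s) in %s: %s", path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) < 2) abort(sprintf("Waveform in %s has fewer than 2 samples.", path))
  dt <- diff(df$t_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    abort(sprintf("Non-uniform time grid in %s (first irregular interval after line %d).",
                  path, n_head + 1 + which.max(abs(dt - stats::median(dt)))))
  }
  vol <- if ("volume_ml" %in% names(df)) df$volume_ml
         else flow_to_volume(df$t_s, df$flow_lps)
  meta$fs <- meta$fs %||% (1 / stats::median(dt))
  new_breath_waveform(df$t_s, df$flow_lps, df$paw_cmh2o, vol, meta)
}
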