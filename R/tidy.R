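#' Tidiers for pcond result objects
#'
#' broom-style accessors: `tidy()` returns the detailed per-element table of
#' a result, `glance()` a one-row summary.
#'
#' @param x An `aop_result`, `agreement_report` or `detector_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @name pcond-tidiers
NULL

#' @rdname pcond-tidiers
#' @export
tidy.aop_result <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname pcond-tidiers
#' @export
glance.aop_result <- function(x, ...) {
  tibble::tibble(method = x$method, closure_detected = x$closure_detected,
                 aop = x$aop, intrinsic_peep = x$intrinsic_peep,
                 sse_ratio = x$sse_ratio)
}

#' @rdname pcond-tidiers
#' @export
tidy.agreement_report <- function(x, ...) {
  attr(x, "data")
}

#' @rdname pcond-tidiers
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname pcond-tidiers
#' @export
tidy.detector_evaluation <- function(x, ...) {
  m <- x$metrics
  long <- tidyr::pivot_longer(m, dplyr::everything(), names_to = "metric",
                              values_to = "value")
  counts <- tidyr::pivot_longer(tibble::as_tibble(unclass_tbl(x$confusion)),
                                dplyr::everything(), names_to = "metric",
                                values_to = "value")
  dplyr::bind_rows(counts, long)
}

#' @rdname pcond-tidiers
#' @export
glance.detector_evaluation <- function(x, ...) {
  out <- dplyr::bind_cols(tibble::as_tibble(unclass_tbl(x$confusion)), x$metrics)
  if (!is.null(x$agreement)) {
    ag <- tibble::as_tibble(unclass_tbl(x$agreement))
    names(ag) <- paste0("aop_", names(ag))
    out <- dplyr::bind_cols(out, ag)
  }
  out$n <- x$n
  out
}

# strip the S3 subclass (and loose attributes) off a classed tibble
unclass_tbl <- function(x) {
  attr(x, "data") <- NULL
  attr(x, "convention") <- NULL
  attr(x, "config") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
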