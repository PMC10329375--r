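#' Confusion matrix for closure detection
#'
#' @param tp,fn,fp,tn Non-negative integer counts (true/false
#'   positives/negatives against the reference method).
#' @return A one-row `confusion_matrix` tibble.
#' @examples
#' compute_metrics(confusion_matrix(51, 4, 15, 143))
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  for (nm in c("tp", "fn", "fp", "tn")) {
    v <- get(nm)
    check_number(v, nm, 0)
    if (abs(v - round(v)) > 1e-9) abort(sprintf("`%s` must be an integer count.", nm))
  }
  if (tp + fn + fp + tn <= 0) abort("Confusion matrix must contain at least one case.")
  out <- tibble::tibble(tp = as.integer(round(tp)), fn = as.integer(round(fn)),
                        fp = as.integer(round(fp)), tn = as.integer(round(tn)))
  class(out) <- c("confusion_matrix", class(out))
  out
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic-performance metrics
#'
#' Standard test-performance metrics of a 2x2 table: sensitivity,
#' specificity, predictive values and diagnostic accuracy (in percent),
#' likelihood ratios, and the Youden index (`sens + spec - 1`, as a
#' fraction). Metrics with a zero denominator are reported as `NA`
#' (undefined), never as an error.
#'
#' @param cm A [confusion_matrix()] (or anything with `tp`, `fn`, `fp`, `tn`
#'   columns).
#' @return A one-row tibble: `sens`, `spec`, `ppv`, `npv`, `accuracy`
#'   (percent, unrounded), `lr_pos`, `lr_neg`, `youden`.
#' @examples
#' compute_metrics(confusion_matrix(51, 4, 15, 143))
#' @export
compute_metrics <- function(cm) {
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(cm)))
  tp <- cm$tp[1]; fn <- cm$fn[1]; fp <- cm$fp[1]; tn <- cm$tn[1]
  sens <- safe_ratio(tp, tp + fn)
  spc <- safe_ratio(tn, tn + fp)
  lr_pos <- if (is.na(spc) || spc == 1) NA_real_ else sens / (1 - spc)
  lr_neg <- if (is.na(spc) || spc == 0) NA_real_ else (1 - sens) / spc
  youden <- sens + spc - 1
  tibble::tibble(
    sens = 100 * sens, spec = 100 * spc,
    ppv = 100 * safe_ratio(tp, tp + fp), npv = 100 * safe_ratio(tn, tn + fn),
    accuracy = 100 * safe_ratio(tp + tn, tp + fn + fp + tn),
    lr_pos = lr_pos, lr_neg = lr_neg,
    youden = youden
  )
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two paired measurement series: bias (mean difference
#' `a - b`), 95% limits of agreement (`bias +/- 1.96 * sd`, sample standard
#' deviation), and the Spearman rank correlation of the pairs (average ranks
#' for ties).
#'
#' @param a,b Equal-length numeric vectors of paired measurements. `a` is
#'   the reference; differences are `a - b`.
#' @return A one-row `agreement_report` tibble: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `spearman_r`, `n`; the per-pair data are kept in
#'   attribute `data` (see [tidy()]).
#' @examples
#' bland_altman(c(10, 12, 9, 13), c(11, 12, 8, 13))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) abort("Bland-Altman analysis needs at least 2 complete pairs.")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b, method = "spearman")
  out <- tibble::tibble(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    sd_diff = s, spearman_r = r, n = n
  )
  attr(out, "data") <- tibble::tibble(a = a, b = b, mean = (a + b) / 2, diff = d)
  attr(out, "convention") <- "differences are a - b (reference minus comparator)"
  class(out) <- c("agreement_report", class(out))
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d pairs (%s)\n  bias %.2f, 95%% limits of agreement [%.2f, %.2f], Spearman r %.2f\n",
    x$n, attr(x, "convention"), x$bias, x$loa_low, x$loa_high, x$spearman_r
  ))
  invisible(x)
}

#' Score a detector against per-case truth
#'
#' Joins truth records and detector calls by case identifier, tabulates
#' closure detection into a confusion matrix (with the usual performance
#' metrics), and runs a Bland-Altman agreement analysis of the AOP values on
#' the cases positive by both. Agreement differences follow the
#' `reference - detector` convention.
#'
#' @param truth A data frame with columns `case_id`, `closure` (logical) and
#'   `aop` (cmH2O, `NA` when no closure).
#' @param calls A data frame with columns `case_id`, `closure_detected`
#'   (logical) and `aop` (reported AOP), e.g. stacked [pcond_method()] rows.
#' @return A `detector_evaluation` list: `confusion` ([confusion_matrix()]),
#'   `metrics` ([compute_metrics()] row), `agreement` ([bland_altman()]
#'   report, or `NULL` when fewer than 2 shared positives), `n`.
#' @export
evaluate_detector <- function(truth, calls) {
  stopifnot(all(c("case_id", "closure", "aop") %in% names(truth)),
            all(c("case_id", "closure_detected", "aop") %in% names(calls)))
  missing_calls <- setdiff(truth$case_id, calls$case_id)
  missing_truth <- setdiff(calls$case_id, truth$case_id)
  if (length(missing_calls) || length(missing_truth)) {
    abort(paste0(
      "Case identifiers do not match.",
      if (length(missing_calls))
        paste0(" No call for: ", paste(missing_calls, collapse = ", "), "."),
      if (length(missing_truth))
        paste0(" No truth for: ", paste(missing_truth, collapse = ", "), ".")
    ))
  }
  j <- dplyr::inner_join(
    dplyr::select(truth, "case_id", truth_closure = "closure", truth_aop = "aop"),
    dplyr::select(calls, "case_id", call_closure = "closure_detected", call_aop = "aop"),
    by = "case_id"
  )
  cm <- confusion_matrix(
    tp = sum(j$truth_closure & j$call_closure),
    fn = sum(j$truth_closure & !j$call_closure),
    fp = sum(!j$truth_closure & j$call_closure),
    tn = sum(!j$truth_closure & !j$call_closure)
  )
  both <- j$truth_closure & j$call_closure
  agreement <- if (sum(both) >= 2) {
    bland_altman(j$truth_aop[both], j$call_aop[both])
  } else {
    NULL
  }
  structure(
    list(confusion = cm, metrics = compute_metrics(cm), agreement = agreement,
         n = nrow(j)),
    class = "detector_evaluation"
  )
}

#' @export
print.detector_evaluation <- function(x, ...) {
  cat(sprintf("<detector_evaluation> %d cases\n", x$n))
  cat(sprintf("  confusion: tp %d, fn %d, fp %d, tn %d\n",
              x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn))
  m <- x$metrics
  cat(sprintf("  sens %.1f%%, spec %.1f%%, ppv %.1f%%, npv %.1f%%, accuracy %.1f%%\n",
              m$sens, m$spec, m$ppv, m$npv, m$accuracy))
  cat(sprintf("  LR+ %.2f, LR- %.2f, Youden %.2f\n", m$lr_pos, m$lr_neg, m$youden))
  if (!is.null(x$agreement)) print(x$agreement)
  else cat("  agreement: undefined (fewer than 2 shared positives)\n")
  invisible(x)
}

#' Reconstruct a 2x2 table from printed metrics
#'
#' Enumerates every integer confusion matrix with the stated margins
#' (`n_positive` reference-positive cases out of `n_total`) and keeps those
#' whose metrics, rounded half-up at the precision implied by each printed
#' value, reproduce all supplied metrics. Useful to recover the exact counts
#' behind a published performance table; an empty result signals
#' inconsistent inputs.
#'
#' @param n_total Total number of cases.
#' @param n_positive Number of reference-positive cases.
#' @param metrics Named list or vector of printed metric values, using the
#'   names of [compute_metrics()] (`sens`, `spec`, `ppv`, `npv`, `accuracy`
#'   in percent, `lr_pos`, `lr_neg`, `youden`). Any subset may be given.
#' @return A `confusion_matrix` tibble with one row per matching table
#'   (possibly zero rows).
#' @examples
#' reconstruct_confusion(213, 55, list(
#'   sens = 93, spec = 91, ppv = 77, npv = 97,
#'   lr_pos = 9.77, lr_neg = 0.08, accuracy = 91, youden = 0.83
#' ))
#' @export
reconstruct_confusion <- function(n_total, n_positive, metrics) {
  check_number(n_total, "n_total", 1)
  check_number(n_positive, "n_positive", 0)
  if (n_positive > n_total) abort("`n_positive` cannot exceed `n_total`.")
  metrics <- as.list(metrics)
  known <- c("sens", "spec", "ppv", "npv", "accuracy", "lr_pos", "lr_neg", "youden")
  bad <- setdiff(names(metrics), known)
  if (length(bad)) abort(paste0("Unknown metric name(s): ", paste(bad, collapse = ", ")))

  n_neg <- n_total - n_positive
  grid <- expand.grid(tp = 0:n_positive, tn = 0:n_neg)
  tp <- grid$tp; tn <- grid$tn
  fn <- n_positive - tp; fp <- n_neg - tn
  sens <- tp / n_positive
  spc <- tn / n_neg
  raw <- list(
    sens = 100 * sens, spec = 100 * spc,
    ppv = ifelse(tp + fp == 0, NA_real_, 100 * tp / (tp + fp)),
    npv = ifelse(tn + fn == 0, NA_real_, 100 * tn / (tn + fn)),
    accuracy = 100 * (tp + tn) / n_total,
    lr_pos = ifelse(spc == 1, NA_real_, sens / (1 - spc)),
    lr_neg = ifelse(spc == 0, NA_real_, (1 - sens) / spc),
    youden = sens + spc - 1
  )

  printed_digits <- function(x) {
    for (d in 0:6) if (abs(x - round(x, d)) < 1e-9) return(d)
    6L
  }
  ok <- rep(TRUE, nrow(grid))
  for (nm in names(metrics)) {
    v <- metrics[[nm]]
    d <- printed_digits(v)
    ok <- ok & !is.na(raw[[nm]]) & abs(round_half_up(raw[[nm]], d) - v) < 1e-9
  }
  hits <- which(ok)
  out <- tibble::tibble(tp = as.integer(tp[hits]), fn = as.integer(fn[hits]),
                        fp = as.integer(fp[hits]), tn = as.integer(tn[hits]))
  class(out) <- c("confusion_matrix", class(out))
  out
}
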