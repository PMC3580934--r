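# Screening-performance evaluation against the GHQ-12 criterion.

#' Confusion counts of the screening score against the GHQ criterion
#'
#' Predicted positive means score >= `cut_point`; condition positive means
#' GHQ >= `ghq_threshold`.
#'
#' @param scores Per-record screening scores.
#' @param ghq Per-record GHQ-12 totals (integers 0..12).
#' @param cut_point Score threshold, default 100.
#' @param ghq_threshold GHQ criterion threshold, default 4.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion(c(120, 80, 120, 80), c(6, 2, 2, 6))
confusion <- function(scores, ghq, cut_point = 100, ghq_threshold = 4) {
  if (length(scores) != length(ghq))
    stopf("scores (%d) and ghq (%d) must have equal length",
          length(scores), length(ghq))
  if (length(ghq) > 0 && !all(ghq %in% 0:12))
    stopf("ghq must be integers in 0..12")
  pred <- scores >= cut_point
  cond <- ghq >= ghq_threshold
  structure(list(tp = sum(pred & cond), tn = sum(!pred & !cond),
                 fp = sum(pred & !cond), fn = sum(!pred & cond)),
            class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the true-positive rate `tp / (tp + fn)`; specificity the
#' true-negative rate `tn / (tn + fp)`. A zero denominator yields `NA` with
#' the corresponding `*_defined` flag set to `FALSE` -- never a silent 0.
#'
#' @param counts A `confusion_counts` (see [confusion()]) or a list with
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @return A list with `sensitivity`, `specificity`,
#'   `sensitivity_defined`, `specificity_defined`.
#' @export
#' @examples
#' sensitivity_specificity(list(tp = 83, fn = 17, tn = 81, fp = 19))
sensitivity_specificity <- function(counts) {
  with(counts, {
    if (any(c(tp, tn, fp, fn) < 0)) stopf("confusion counts must be >= 0")
    sens_def <- (tp + fn) > 0
    spec_def <- (tn + fp) > 0
    list(sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
         specificity = if (spec_def) tn / (tn + fp) else NA_real_,
         sensitivity_defined = sens_def,
         specificity_defined = spec_def)
  })
}

#' Full screening evaluation report
#'
#' @inheritParams confusion
#' @return A list of class `screening_report`: counts, metrics, and the
#'   thresholds used.
#' @export
evaluate_screening <- function(scores, ghq, cut_point = 100,
                               ghq_threshold = 4) {
  counts <- confusion(scores, ghq, cut_point, ghq_threshold)
  metrics <- sensitivity_specificity(counts)
  structure(c(list(counts = counts), metrics,
              list(cut_point = cut_point, ghq_threshold = ghq_threshold,
                   n = counts$tp + counts$tn + counts$fp + counts$fn)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening evaluation (n = %d, cut point %s, GHQ >= %s)\n",
              x$n, format(x$cut_point), format(x$ghq_threshold)))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n",
              x$counts$tp, x$counts$fn, x$counts$tn, x$counts$fp))
  cat(sprintf("  sensitivity %s  specificity %s\n",
              if (x$sensitivity_defined) sprintf("%.3f", x$sensitivity)
              else "undefined",
              if (x$specificity_defined) sprintf("%.3f", x$specificity)
              else "undefined"))
  invisible(x)
}
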