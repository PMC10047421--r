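#' Lesion-level detection metrics
#'
#' Precision `tp / (tp + fp)`, recall `tp / (tp + fn)`, and their harmonic
#' mean F1. TP/FN count ground-truth fracture components that are / are not
#' matched by a detection; FP counts detections with no matching component.
#' When a denominator is zero (and hence tp = 0) the corresponding ratio is
#' 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param dice Optional aggregate pixel Dice to carry alongside the counts.
#' @return An object of class `metrics_report` with fields `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`, and `dice` (NA if not supplied).
#' @export
detection_metrics <- function(tp, fp, fn, dice = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 dice = dice),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f", x$precision,
              x$recall, x$f1))
  if (!is.na(x$dice)) cat(sprintf("  pixel Dice %.4f", x$dice))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
             recall = x$recall, f1 = x$f1, dice = x$dice)
}
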