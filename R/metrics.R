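#' Confusion counts
#'
#' Container for the four classification outcomes used to score the sensor,
#' with positive = multiple nest occupation: true positive (multiple
#' correctly detected), false positive (multiple flagged but one hen),
#' true negative (single correctly detected), false negative (multiple
#' missed).
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_input("confusion counts must be non-negative integers")
  }
  out <- as.list(as.integer(counts))
  names(out) <- names(counts)
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, TN %d, FN %d (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Build confusion counts from predicted/true label pairs
#'
#' @param predicted,truth equal-length 0/1 vectors (1 = multiple occupation).
#' @return A [confusion_counts()]; the four counts sum to the vector length.
#' @export
confusion_from_pairs <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_input("predicted and truth must have the same length")
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop_input("predicted and truth must be 0/1")
  }
  confusion_counts(tp = sum(predicted == 1 & truth == 1),
                   fp = sum(predicted == 1 & truth == 0),
                   tn = sum(predicted == 0 & truth == 0),
                   fn = sum(predicted == 0 & truth == 1))
}

#' Sensitivity and specificity of the sensor
#'
#' `sensitivity()` is `100 * TP / (FN + TP)`, the share of multiple
#' occupations correctly detected; `specificity()` is `100 * TN / (FP + TN)`,
#' the share of single occupations correctly passed.  Both are computed in
#' exact arithmetic and rounded half-up to one decimal, the sensor's
#' reporting convention.
#'
#' @param c a [confusion_counts()].
#' @return Percentage in \[0, 100\], one decimal.
#' @examples
#' sensitivity(confusion_counts(tp = 45, fp = 6, tn = 125, fn = 2))  # 95.7
#' specificity(confusion_counts(tp = 45, fp = 6, tn = 125, fn = 2))  # 95.4
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0L) stop_input("sensitivity undefined: TP + FN = 0")
  round_half_up(100 * c$tp / (c$fn + c$tp), 1)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tn + c$fp == 0L) stop_input("specificity undefined: TN + FP = 0")
  round_half_up(100 * c$tn / (c$fp + c$tn), 1)
}
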