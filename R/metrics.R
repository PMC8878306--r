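#' Confusion counts for resistant / non-resistant predictions
#'
#' `resistant` is the positive class.
#'
#' @param labels character vector of true labels
#'   (`"resistant"` / `"non_resistant"`).
#' @param preds same-length vector of predicted labels.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN` (sums to the input
#'   length).
#' @examples
#' confusion(c("resistant", "non_resistant"), c("resistant", "non_resistant"))
#' @export
confusion <- function(labels, preds) {
  if (length(labels) != length(preds) || length(labels) < 1)
    stop("input error: labels and predictions must have equal positive length")
  pos <- labels == "resistant"
  ppos <- preds == "resistant"
  c(TP = sum(pos & ppos), TN = sum(!pos & !ppos),
    FP = sum(!pos & ppos), FN = sum(pos & !ppos))
}

#' Classification measures from confusion counts
#'
#' Accuracy `(TP+TN)/total`; Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any denominator factor is 0; F1 as the harmonic mean of precision and
#' sensitivity (0 when undefined); and the Hybrid measure
#' `Sensitivity + delta * Specificity`, where `delta` is the
#' positives-to-negatives ratio of the training labels.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (see [confusion()]).
#' @param which one of `"Acc"`, `"MCC"`, `"F1"`, `"Hybrid"`.
#' @param delta positives:negatives ratio; required for `"Hybrid"`.
#' @return Scalar measure value.
#' @examples
#' measure(c(TP = 87, FN = 46, TN = 435, FP = 42), "MCC")
#' @export
measure <- function(counts, which = c("Acc", "MCC", "F1", "Hybrid"),
                    delta = NULL) {
  which <- match.arg(which)
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  total <- TP + TN + FP + FN
  if (total < 1) stop("input error: empty confusion counts")
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  switch(which,
    Acc = (TP + TN) / total,
    MCC = {
      den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
      if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
    },
    F1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
    Hybrid = {
      if (is.null(delta)) stop("Hybrid requires delta (positives:negatives ratio)")
      sens + delta * spec
    })
}

#' Full evaluation report from labels and predictions
#'
#' Confusion counts plus the six derived measures (Accuracy, Sensitivity,
#' Specificity, MCC, Precision, F1).
#'
#' @param labels,preds as in [confusion()].
#' @return List with `counts` and `measures` (named numeric vectors).
#' @export
evaluation_report <- function(labels, preds) {
  ct <- confusion(labels, preds)
  TP <- ct[["TP"]]; TN <- ct[["TN"]]; FP <- ct[["FP"]]; FN <- ct[["FN"]]
  list(counts = ct, measures = c(
    Accuracy = measure(ct, "Acc"),
    Sensitivity = if (TP + FN > 0) TP / (TP + FN) else 0,
    Specificity = if (TN + FP > 0) TN / (TN + FP) else 0,
    MCC = measure(ct, "MCC"),
    Precision = if (TP + FP > 0) TP / (TP + FP) else 0,
    F1 = measure(ct, "F1")))
}

#' Write an evaluation report as JSON
#'
#' @param report output of [evaluation_report()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(report, path) {
  jsonlite::write_json(list(counts = as.list(report$counts),
                            measures = as.list(report$measures)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
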