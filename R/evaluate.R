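#' Build a binary confusion matrix
#'
#' Counts the four outcomes of binary predictions against truth. For the
#' PD-vs-HC task the cells are: `tPos` = T_PD (PD correctly called PD),
#' `tNeg` = T_HC, `fNeg` = F_HC (PD missed as HC), `fPos` = F_PD (HC called
#' PD).
#'
#' @param predicted predicted labels, 0/1 (1 = positive).
#' @param truth true labels, 0/1, same length.
#' @param positive,negative class display names.
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(predicted, truth, positive = "PD",
                            negative = "HC") {
  if (length(predicted) != length(truth))
    stop("predicted and truth have different lengths (",
         length(predicted), " vs ", length(truth), ")")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be 0/1")
  new("ConfusionMatrix",
      tPos = sum(predicted == 1 & truth == 1),
      tNeg = sum(predicted == 0 & truth == 0),
      fPos = sum(predicted == 1 & truth == 0),
      fNeg = sum(predicted == 0 & truth == 1),
      positive = positive, negative = negative)
}

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tNeg, object@fPos, object@fNeg, object@tPos), 2, 2,
              dimnames = list(predicted = c(object@negative, object@positive),
                              truth = c(object@negative, object@positive)))
  cat("ConfusionMatrix (n =", sum(m), ")\n")
  print(m)
})

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, specificity (percentages) and the F1 score
#' (harmonic mean of precision and recall, on the percentage scale):
#' \deqn{Acc = (T_{HC}+T_{PD})/n \times 100, \quad
#'       Pre = T_{PD}/(T_{PD}+F_{PD}) \times 100,}
#' \deqn{Rec = T_{PD}/(T_{PD}+F_{HC}) \times 100, \quad
#'       Spe = T_{HC}/(T_{HC}+F_{PD}) \times 100, \quad
#'       F1 = 2 \cdot Pre \cdot Rec / (Pre + Rec).}
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0 or 100. Values are returned at full precision; round to 2 decimals
#' for reporting.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named list: `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1` (percent scale).
#' @examples
#' cm <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' classificationMetrics(cm)
#' @export
classificationMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  n <- cm@tPos + cm@tNeg + cm@fPos + cm@fNeg
  if (n == 0) stop("empty confusion matrix")
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  pre <- frac(cm@tPos, cm@tPos + cm@fPos)
  rec <- frac(cm@tPos, cm@tPos + cm@fNeg)
  f1 <- if (is.na(pre) || is.na(rec) || pre + rec == 0) NA_real_
        else 2 * pre * rec / (pre + rec)
  list(accuracy = frac(cm@tPos + cm@tNeg, n),
       precision = pre, recall = rec,
       specificity = frac(cm@tNeg, cm@tNeg + cm@fPos),
       f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean on whatever scale its inputs share (percent in the
#' reports).
#'
#' @param precision,recall scalar values.
#' @return the F1 score.
#' @export
f1Score <- function(precision, recall)
  2 * precision * recall / (precision + recall)

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over every distinct score to trace the ROC
#' curve, and computes the AUC as the probability that a random positive
#' sample outscores a random negative one (ties count 1/2; rank
#' formulation), which equals the trapezoidal area under the curve.
#'
#' @param scores positive-class scores.
#' @param labels true labels, 0/1; both classes must be present.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels have different lengths")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("rocAuc requires both classes present (labels 0/1)")
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(scores >= t & labels == 0) / nNeg,
                 numeric(1)),
    tpr = vapply(th, function(t) sum(scores >= t & labels == 1) / nPos,
                 numeric(1))
  )
  list(curve = curve, auc = auc)
}
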