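#' Degree of correct prediction
#'
#' Folds the predicted positive-class probability and the true binary label
#' into a single number `p'`: the probability the model assigned to the
#' *true* class. `p' = 1` is a perfectly correct prediction, `p' = 0`
#' perfectly wrong, and `p' = 0.5` completely random.
#'
#' @param pPlus predicted probability of the positive class, in `[0, 1]`.
#' @param y true label, 0 or 1 (vectorized; recycled against `pPlus`).
#' @return `pPlus` where `y == 1`, `1 - pPlus` where `y == 0`.
#' @export
degreeOfCorrectPrediction <- function(pPlus, y) {
  if (any(pPlus < 0 | pPlus > 1)) stop("pPlus must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1")
  ifelse(y == 1, pPlus, 1 - pPlus)
}

clampProb <- function(p) pmax(p, .Machine$double.eps)

#' Loss family: cross-entropy, focal and improved focal loss
#'
#' All three losses act on the degree of correct prediction `p'` (see
#' [degreeOfCorrectPrediction()]) and use the natural logarithm:
#'
#' * `crossEntropy(p') = -log p'`
#' * `focalLoss(p', gamma) = (1 - p')^gamma * (-log p')` — the focusing
#'   coefficient down-weights easy samples.
#' * `improvedFocalLoss(p', tau) = (1 - p'^2) * (-log p')` for `p' >= tau`,
#'   and exactly 0 for `p' < tau` — the convex coefficient decays slowly on
#'   hard samples and fast on easy ones, and samples below the outlier
#'   threshold `tau` (default 0.05) are discarded from learning entirely.
#'
#' `p' = 0` is clamped to machine epsilon before the logarithm for
#' `crossEntropy` and `focalLoss`; `improvedFocalLoss` already returns 0
#' below `tau`.
#'
#' @param pPrime degree of correct prediction, in `[0, 1]` (vectorized).
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @param tau outlier threshold in `[0, 0.5)` (default 0.05); the formula
#'   applies at exactly `p' = tau` (strict inequality defines the cutoff).
#' @return per-sample loss values, `>= 0`.
#' @examples
#' crossEntropy(0.5)                 # log 2
#' improvedFocalLoss(c(0.04, 0.5))   # 0, 0.75 * log 2
#' @export
crossEntropy <- function(pPrime) {
  if (any(pPrime < 0 | pPrime > 1)) stop("pPrime must lie in [0, 1]")
  -log(clampProb(pPrime))
}

#' @rdname crossEntropy
#' @export
focalLoss <- function(pPrime, gamma = 2) {
  if (any(pPrime < 0 | pPrime > 1)) stop("pPrime must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  (1 - pPrime)^gamma * -log(clampProb(pPrime))
}

#' @rdname crossEntropy
#' @export
improvedFocalLoss <- function(pPrime, tau = 0.05) {
  if (any(pPrime < 0 | pPrime > 1)) stop("pPrime must lie in [0, 1]")
  if (tau < 0 || tau >= 0.5) stop("tau must lie in [0, 0.5)")
  ifelse(pPrime < tau, 0, (1 - pPrime^2) * -log(clampProb(pPrime)))
}

# d(loss)/d(pPrime), used by the training loop
lossGradient <- function(pPrime, type = c("improved_focal", "cross_entropy",
                                          "focal"),
                         gamma = 2, tau = 0.05) {
  type <- match.arg(type)
  p <- clampProb(pPrime)
  switch(type,
    cross_entropy = -1 / p,
    focal = -gamma * (1 - p)^(gamma - 1) * -log(p) - (1 - p)^gamma / p,
    improved_focal = ifelse(pPrime < tau, 0, -2 * p * -log(p) - (1 - p^2) / p)
  )
}

#' Epoch loss
#'
#' The loss reported per epoch is the arithmetic mean of the per-sample
#' losses in that epoch.
#'
#' @param perSampleLosses non-empty numeric vector.
#' @return scalar mean.
#' @export
epochLoss <- function(perSampleLosses) {
  if (length(perSampleLosses) == 0) stop("no per-sample losses supplied")
  mean(perSampleLosses)
}
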