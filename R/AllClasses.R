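#' Cohort generator configuration
#'
#' Describes the synthetic gait cohort to simulate: group sizes, the
#' per-condition feature block sizes, and the class-separation parameters.
#' Defaults reproduce the study design: 296 PD subjects (230 early, 66
#' moderate-to-advanced by Hoehn–Yahr stage) and 161 healthy controls, each
#' with 97 TUG + 7 TURN + 86 NARROW gait features and 4 demographics
#' (sex, age, thigh length, lower-leg length), 194 features in total.
#'
#' @slot nPD,nHC number of PD / healthy-control subjects.
#' @slot nEarly,nModAdv PD severity subgroup sizes; must sum to `nPD`.
#' @slot nTug,nTurn,nNarrow,nDemo feature block sizes.
#' @slot effectSize standardized mean shift (in SDs) between PD and HC on the
#'   discriminative gait features.
#' @slot subgroupEffect additional shift for the moderate-to-advanced group.
#' @slot shiftFraction fraction of each gait block that carries the shift.
#' @slot correlation within-block equicorrelation in `[0, 1)`.
#' @slot noiseSD marginal standard deviation of the gait features.
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nPD = "numeric", nHC = "numeric",
    nEarly = "numeric", nModAdv = "numeric",
    nTug = "numeric", nTurn = "numeric", nNarrow = "numeric",
    nDemo = "numeric",
    effectSize = "numeric", subgroupEffect = "numeric",
    shiftFraction = "numeric", correlation = "numeric",
    noiseSD = "numeric", seed = "numeric"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  counts <- c(
    nPD = object@nPD, nHC = object@nHC,
    nEarly = object@nEarly, nModAdv = object@nModAdv,
    nTug = object@nTug, nTurn = object@nTurn,
    nNarrow = object@nNarrow, nDemo = object@nDemo
  )
  if (any(counts < 0) || any(counts != round(counts)))
    msg <- c(msg, "all counts must be non-negative integers")
  if (object@nEarly + object@nModAdv != object@nPD)
    msg <- c(msg, "nEarly + nModAdv must equal nPD")
  if (object@correlation < 0 || object@correlation >= 1)
    msg <- c(msg, "correlation must lie in [0, 1)")
  if (object@noiseSD <= 0)
    msg <- c(msg, "noiseSD must be > 0")
  if (object@shiftFraction < 0 || object@shiftFraction > 1)
    msg <- c(msg, "shiftFraction must lie in [0, 1]")
  if (object@effectSize < 0 || object@subgroupEffect < 0)
    msg <- c(msg, "effect sizes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gait feature cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one `features`
#' assay (features in rows, subjects in columns) plus per-subject metadata:
#' `diagnosis` (HC/PD), `severity` (none/early/moderate_advanced) and a
#' `synthetic` flag marking SMOTE-generated samples. `severity` is `none`
#' exactly for HC subjects.
#'
#' @seealso [generateCohort()], [featureMatrix()], [diagnosis()]
#' @export
setClass("GaitCohort", contains = "SummarizedExperiment")

setValidity("GaitCohort", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("subject_id", "diagnosis", "severity", "synthetic")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!"features" %in% assayNames(object))
    return("assay 'features' is required")
  x <- assay(object, "features")
  if (anyNA(x) || any(!is.finite(x)))
    msg <- c(msg, "feature values must be finite and non-missing")
  if (!all(cd$diagnosis %in% c("HC", "PD")))
    msg <- c(msg, "diagnosis must be 'HC' or 'PD'")
  if (!all(cd$severity %in% c("none", "early", "moderate_advanced")))
    msg <- c(msg, "severity must be none/early/moderate_advanced")
  bad <- (cd$diagnosis == "HC") != (cd$severity == "none")
  if (any(bad))
    msg <- c(msg, "severity must be 'none' iff diagnosis is 'HC'")
  if (length(msg)) msg else TRUE
})

#' Min-max feature normalizer
#'
#' Per-feature minima and ranges learned on the training partition; values
#' map to `[0, 1]`, constant features map to 0, and out-of-range values at
#' application time are clipped.
#'
#' @slot mins,ranges numeric vectors, one entry per feature.
#' @slot featureNames names of the features the normalizer was fit on.
#' @seealso [fitNormalizer()], [applyNormalizer()]
#' @export
setClass("MinMaxNormalizer",
  representation(mins = "numeric", ranges = "numeric",
                 featureNames = "character")
)

#' Residual network
#'
#' A from-scratch residual convolutional network for single-channel square
#' images: a 1x1 convolution stem, three residual layers (two units each,
#' the first unit of each layer downsampling by stride 2 with a 1x1
#' projection shortcut), adaptive global average pooling to a channel
#' descriptor, and a 2-neuron linear head with sigmoid outputs.
#'
#' @slot spec list describing the architecture (see [networkSpec()]).
#' @slot params nested list of weight/bias/batch-norm parameters.
#' @slot buffers nested list of batch-norm running statistics.
#' @slot seed integer seed used for initialization.
#' @seealso [buildNetwork()], [netForward()]
#' @export
setClass("ResidualNet",
  representation(spec = "list", params = "list", buffers = "list",
                 seed = "numeric")
)

#' Binary confusion matrix
#'
#' The four counts of a binary classification outcome: `tPos`/`tNeg` are
#' correctly classified positive/negative samples, `fNeg` positives predicted
#' negative, `fPos` negatives predicted positive. For the PD-vs-HC task these
#' are T_PD, T_HC, F_HC and F_PD respectively.
#'
#' @slot tPos,tNeg,fPos,fNeg non-negative counts.
#' @slot positive,negative class display names.
#' @seealso [confusionCounts()], [classificationMetrics()]
#' @export
setClass("ConfusionMatrix",
  representation(tPos = "numeric", tNeg = "numeric",
                 fPos = "numeric", fNeg = "numeric",
                 positive = "character", negative = "character")
)

setValidity("ConfusionMatrix", function(object) {
  cnt <- c(object@tPos, object@tNeg, object@fPos, object@fNeg)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    "counts must be non-negative integers" else TRUE
})
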