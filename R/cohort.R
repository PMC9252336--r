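#' Create a cohort generator configuration
#'
#' Defaults emulate the study design: 296 PD (230 early / 66
#' moderate-to-advanced) and 161 age-matched HC subjects, 97 + 7 + 86 gait
#' features from the TUG, TURN and NARROW test conditions plus 4
#' demographics. Class separation is a standardized mean shift of
#' `effectSize` SDs applied to the leading `shiftFraction` of each gait
#' block; moderate-to-advanced subjects are shifted a further
#' `subgroupEffect` SDs on the same features. Gait features within a block
#' are equicorrelated Gaussians.
#'
#' @param nPD,nHC group sizes.
#' @param nEarly,nModAdv PD severity subgroup sizes (sum to `nPD`).
#' @param nTug,nTurn,nNarrow,nDemo feature block sizes.
#' @param effectSize standardized PD-vs-HC shift in SD units.
#' @param subgroupEffect additional shift for moderate-to-advanced PD.
#' @param shiftFraction fraction of each gait block carrying the shift.
#' @param correlation within-block equicorrelation, in `[0, 1)`.
#' @param noiseSD marginal SD of the gait features.
#' @param seed integer RNG seed.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' @export
cohortConfig <- function(nPD = 296, nHC = 161, nEarly = 230, nModAdv = 66,
                         nTug = 97, nTurn = 7, nNarrow = 86, nDemo = 4,
                         effectSize = 1.0, subgroupEffect = 0.5,
                         shiftFraction = 0.3, correlation = 0.3,
                         noiseSD = 1.0, seed = 1L) {
  new("CohortConfig",
      nPD = nPD, nHC = nHC, nEarly = nEarly, nModAdv = nModAdv,
      nTug = nTug, nTurn = nTurn, nNarrow = nNarrow, nDemo = nDemo,
      effectSize = effectSize, subgroupEffect = subgroupEffect,
      shiftFraction = shiftFraction, correlation = correlation,
      noiseSD = noiseSD, seed = as.numeric(seed))
}

# canonical feature names: tug_001..tug_097, turn_001.., nar_001.., demographics
gaitFeatureNames <- function(nTug = 97, nTurn = 7, nNarrow = 86, nDemo = 4) {
  pad <- function(prefix, n)
    if (n > 0) sprintf("%s_%03d", prefix, seq_len(n)) else character()
  demo <- c("sex", "age", "thigh_len", "shank_len")
  if (nDemo > length(demo))
    demo <- c(demo, sprintf("demo_%03d", seq_len(nDemo - length(demo))))
  c(pad("tug", nTug), pad("turn", nTurn), pad("nar", nNarrow),
    demo[seq_len(nDemo)])
}

# indices (within the gait blocks) of the features that carry the class shift:
# the leading round(fraction * blockSize) features of each block
shiftedFeatureIndex <- function(config) {
  sizes <- c(config@nTug, config@nTurn, config@nNarrow)
  offs <- cumsum(c(0, sizes[-3]))
  unlist(lapply(seq_along(sizes), function(b) {
    m <- floor(config@shiftFraction * sizes[b] + 0.5)
    if (m > 0) offs[b] + seq_len(m) else integer()
  }))
}

#' Generate a synthetic gait cohort
#'
#' Simulates the per-subject feature table: gait blocks are equicorrelated
#' multivariate Gaussians (shared-factor construction), PD subjects are
#' shifted by `effectSize` SDs on the discriminative features, and
#' moderate-to-advanced PD by a further `subgroupEffect` SDs. Demographics
#' are sex ~ Bernoulli(0.5), age ~ N(65, 8) (identical across classes —
#' age-matched controls), thigh length ~ N(45, 3) cm and lower-leg length
#' ~ N(40, 3) cm. Identical seeds give bit-identical cohorts.
#'
#' @param config a [CohortConfig-class], e.g. from [cohortConfig()].
#' @return a [GaitCohort-class] with `nPD + nHC` subjects and
#'   `nTug + nTurn + nNarrow + nDemo` features (194 by default).
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 7))
#' table(diagnosis(cohort))
#' @export
generateCohort <- function(config = cohortConfig()) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nPD + config@nHC
  diagnosisLab <- c(rep("PD", config@nPD), rep("HC", config@nHC))
  severityLab <- c(rep("early", config@nEarly),
                   rep("moderate_advanced", config@nModAdv),
                   rep("none", config@nHC))

  sizes <- c(config@nTug, config@nTurn, config@nNarrow)
  nGait <- sum(sizes)
  rho <- config@correlation

  # equicorrelated block: x = sqrt(rho) * shared + sqrt(1 - rho) * idio
  gait <- matrix(0.0, n, nGait)
  off <- 0
  for (b in seq_along(sizes)) {
    d <- sizes[b]
    if (d == 0) next
    shared <- rnorm(n)
    idio <- matrix(rnorm(n * d), n, d)
    gait[, off + seq_len(d)] <-
      (sqrt(rho) * shared + sqrt(1 - rho) * idio) * config@noiseSD
    off <- off + d
  }

  shiftIdx <- shiftedFeatureIndex(config)
  if (length(shiftIdx)) {
    delta <- config@effectSize * config@noiseSD
    deltaSub <- config@subgroupEffect * config@noiseSD
    isPD <- diagnosisLab == "PD"
    isModAdv <- severityLab == "moderate_advanced"
    gait[isPD, shiftIdx] <- gait[isPD, shiftIdx] + delta
    gait[isModAdv, shiftIdx] <- gait[isModAdv, shiftIdx] + deltaSub
  }

  demo <- cbind(
    sex = rbinom(n, 1, 0.5),
    age = rnorm(n, 65, 8),
    thigh_len = rnorm(n, 45, 3),
    shank_len = rnorm(n, 40, 3)
  )[, seq_len(min(4, config@nDemo)), drop = FALSE]
  if (config@nDemo > 4)
    demo <- cbind(demo, matrix(rnorm(n * (config@nDemo - 4)), n))

  features <- cbind(gait, demo)
  colnames(features) <- gaitFeatureNames(config@nTug, config@nTurn,
                                         config@nNarrow, config@nDemo)
  subjectId <- sprintf("S%04d", seq_len(n))
  rownames(features) <- subjectId

  newGaitCohort(t(features),
    DataFrame(subject_id = subjectId,
              diagnosis = diagnosisLab,
              severity = severityLab,
              synthetic = rep(FALSE, n),
              row.names = subjectId),
    metadata = list(config = config, seed = config@seed))
}

newGaitCohort <- function(featuresByColumn, colData, metadata = list()) {
  rd <- DataFrame(
    block = vapply(rownames(featuresByColumn), function(nm) {
      if (startsWith(nm, "tug_")) "tug"
      else if (startsWith(nm, "turn_")) "turn"
      else if (startsWith(nm, "nar_")) "nar"
      else "demo"
    }, character(1)),
    row.names = rownames(featuresByColumn)
  )
  se <- SummarizedExperiment(
    assays = list(features = featuresByColumn),
    colData = colData, rowData = rd
  )
  metadata(se) <- metadata
  obj <- new("GaitCohort", se)
  validObject(obj)
  obj
}

#' @rdname gaitPD-accessors
#' @export
setMethod("diagnosis", "GaitCohort", function(x) colData(x)$diagnosis)

#' @rdname gaitPD-accessors
#' @export
setMethod("severity", "GaitCohort", function(x) colData(x)$severity)

#' @rdname gaitPD-accessors
#' @export
setMethod("isSynthetic", "GaitCohort", function(x) colData(x)$synthetic)

#' @rdname gaitPD-accessors
#' @export
setMethod("featureMatrix", "GaitCohort", function(x) t(assay(x, "features")))

setMethod("show", "GaitCohort", function(object) {
  cat("GaitCohort:", ncol(object), "subjects x", nrow(object), "features\n")
  cat("  diagnosis: ", paste(sprintf("%s=%d", names(table(diagnosis(object))),
                                     table(diagnosis(object))),
                             collapse = ", "), "\n", sep = "")
  sv <- table(severity(object))
  cat("  severity:  ", paste(sprintf("%s=%d", names(sv), sv), collapse = ", "),
      "\n", sep = "")
  if (any(isSynthetic(object)))
    cat("  synthetic samples:", sum(isSynthetic(object)), "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: ", object@nPD, " PD (", object@nEarly, " early / ",
      object@nModAdv, " mod-adv) + ", object@nHC, " HC; ",
      object@nTug + object@nTurn + object@nNarrow + object@nDemo,
      " features\n", sep = "")
  cat("  effectSize=", object@effectSize,
      " subgroupEffect=", object@subgroupEffect,
      " shiftFraction=", object@shiftFraction,
      " correlation=", object@correlation,
      " noiseSD=", object@noiseSD,
      " seed=", object@seed, "\n", sep = "")
})

#' Write / read a cohort as CSV
#'
#' The CSV has one row per subject with columns `subject_id`, the 194
#' feature columns by name, then `diagnosis` and `severity`. The round trip
#' preserves values at full precision; reading realigns feature columns by
#' header name, so column order in the file is immaterial.
#'
#' @param cohort a [GaitCohort-class].
#' @param path file path.
#' @return `cohortToCsv` returns `path` invisibly; `csvToCohort` a
#'   [GaitCohort-class].
#' @export
cohortToCsv <- function(cohort, path) {
  stopifnot(is(cohort, "GaitCohort"))
  df <- data.frame(subject_id = colData(cohort)$subject_id,
                   featureMatrix(cohort),
                   diagnosis = diagnosis(cohort),
                   severity = severity(cohort),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohortToCsv
#' @param featureNames expected feature columns; defaults to the canonical
#'   194-feature schema.
#' @export
csvToCohort <- function(path, featureNames = gaitFeatureNames()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", featureNames, "diagnosis", "severity")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(df), need)
  if (length(extra))
    stop("cohort CSV has unexpected column(s): ", paste(extra, collapse = ", "))
  x <- as.matrix(df[, featureNames, drop = FALSE])
  if (!is.numeric(x) || anyNA(x))
    stop("non-numeric or missing feature values in cohort CSV")
  rownames(x) <- df$subject_id
  newGaitCohort(t(x),
    DataFrame(subject_id = df$subject_id,
              diagnosis = df$diagnosis,
              severity = df$severity,
              synthetic = rep(FALSE, nrow(df)),
              row.names = df$subject_id))
}
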