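#' Balance a two-class cohort with SMOTE
#'
#' Synthetic minority oversampling: each synthetic sample is a random
#' interpolation `x + u * (x_nn - x)` between a minority sample `x` and one
#' of its `k` nearest minority-class neighbors (Euclidean distance on the
#' feature vectors), with `u ~ Uniform(0, 1)`. Enough synthetic samples are
#' added to bring the minority class up to the majority count; original
#' samples are returned unchanged and synthetic ones carry
#' `isSynthetic() == TRUE`. Synthetic samples inherit the diagnosis and
#' severity labels of their base sample.
#'
#' @param cohort a [GaitCohort-class].
#' @param k number of nearest neighbors to interpolate towards (default 5).
#' @param labels binary class labels defining minority/majority; defaults to
#'   `diagnosis(cohort)`. Severity-based tasks pass `severity(cohort)`.
#' @param seed optional seed for the interpolation draws.
#' @return a [GaitCohort-class] with both classes at the majority count.
#' @examples
#' balanced <- smoteBalance(generateCohort(cohortConfig(seed = 1)), seed = 2)
#' table(diagnosis(balanced))
#' @export
smoteBalance <- function(cohort, k = 5, labels = diagnosis(cohort),
                         seed = NULL) {
  stopifnot(is(cohort, "GaitCohort"))
  if (!is.null(seed)) set.seed(seed)
  tab <- table(labels)
  if (length(tab) != 2)
    stop("smoteBalance requires exactly two classes; found ",
         length(tab), " (", paste(names(tab), collapse = ", "), ")")
  if (tab[1] == tab[2]) return(cohort)

  minority <- names(tab)[which.min(tab)]
  nSynth <- abs(diff(as.integer(tab)))
  minIdx <- which(labels == minority)
  m <- length(minIdx)
  if (m <= k)
    stop("minority class has ", m, " samples but k = ", k,
         "; choose k < minority class size")

  X <- featureMatrix(cohort)
  M <- X[minIdx, , drop = FALSE]
  D <- as.matrix(dist(M))
  diag(D) <- Inf
  # k nearest minority neighbors of each minority sample (m x k)
  nnIdx <- t(matrix(apply(D, 1, function(d) order(d)[seq_len(k)]), nrow = k))

  base <- if (nSynth <= m) sample.int(m, nSynth)
          else sample.int(m, nSynth, replace = TRUE)
  pick <- nnIdx[cbind(base, sample.int(k, nSynth, replace = TRUE))]
  u <- runif(nSynth)
  synth <- M[base, , drop = FALSE] +
    u * (M[pick, , drop = FALSE] - M[base, , drop = FALSE])

  synthId <- sprintf("syn_%04d", seq_len(nSynth))
  rownames(synth) <- synthId
  cd <- colData(cohort)
  baseRows <- minIdx[base]
  cdSynth <- DataFrame(subject_id = synthId,
                       diagnosis = cd$diagnosis[baseRows],
                       severity = cd$severity[baseRows],
                       synthetic = rep(TRUE, nSynth),
                       row.names = synthId)
  newGaitCohort(cbind(assay(cohort, "features"), t(synth)),
                rbind(cd[, c("subject_id", "diagnosis", "severity",
                             "synthetic")], cdSynth),
                metadata = metadata(cohort))
}
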