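#' @name gaitPD-accessors
#' @title Accessors for gait cohort objects
#' @param x a [GaitCohort-class] object.
#' @return `diagnosis` and `severity` return character vectors (one entry per
#'   subject); `isSynthetic` a logical vector; `featureMatrix` a numeric
#'   subjects x features matrix (the transpose of the stored assay, ready for
#'   row-wise preprocessing).
NULL

#' @rdname gaitPD-accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))

#' @rdname gaitPD-accessors
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))

#' @rdname gaitPD-accessors
#' @export
setGeneric("isSynthetic", function(x) standardGeneric("isSynthetic"))

#' @rdname gaitPD-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
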