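#' Arm identifiers of an object
#' @param x an object carrying chromosome-arm annotation.
#' @return character vector of arm identifiers (e.g. \code{"8q"}).
#' @export
setGeneric("armIds", function(x) standardGeneric("armIds"))

#' Sample identifiers of an object
#' @param x an object carrying per-sample data.
#' @return character vector of sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Library sizes (total included-arm read counts) per sample
#' @param x an \linkS4class{ArmCounts}.
#' @return named integer vector of per-sample totals.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' Aneuploidy scores of a result object
#' @param x an \linkS4class{AneuploidyResults}.
#' @return named numeric vector of scores, in control-SD units.
#' @export
setGeneric("aneuploidyScores", function(x) standardGeneric("aneuploidyScores"))

#' Dichotomized score classes of a result object
#' @param x an \linkS4class{AneuploidyResults}.
#' @return factor with levels \code{low}, \code{high}.
#' @export
setGeneric("scoreClasses", function(x) standardGeneric("scoreClasses"))

#' @export
setMethod("armIds", "RangedSummarizedExperiment",
          function(x) as.character(SummarizedExperiment::rowData(x)$arm_id))

#' @export
setMethod("sampleIds", "RangedSummarizedExperiment",
          function(x) colnames(x))

#' @export
setMethod("librarySizes", "ArmCounts", function(x)
  colSums(SummarizedExperiment::assay(x, "counts")))

#' @export
setMethod("armIds", "ControlPanel", function(x) x@armIds)

#' @export
setMethod("armIds", "AneuploidyResults", function(x) x@armIds)

#' @export
setMethod("sampleIds", "AneuploidyResults", function(x) x@sampleIds)

#' @export
setMethod("aneuploidyScores", "AneuploidyResults",
          function(x) setNames(x@scores, x@sampleIds))

#' @export
setMethod("scoreClasses", "AneuploidyResults",
          function(x) setNames(x@classes, x@sampleIds))
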