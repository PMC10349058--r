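#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Per-arm read counts for a set of samples
#'
#' \code{ArmCounts} extends
#' \linkS4class{RangedSummarizedExperiment}: rows are the included
#' chromosome arms (as genomic ranges carrying \code{arm_id}), columns are
#' samples, and the \code{"counts"} assay holds raw per-arm read counts.
#' Library size of a sample is defined as its column sum over the included
#' arms. Acrocentric short arms (13p, 14p, 15p, 21p, 22p) and chromosome Y
#' never appear among the rows.
#'
#' @seealso [armCounts()], [normalizeToFractions()], [countReadsPerArm()]
#' @export
setClass("ArmCounts", contains = "RangedSummarizedExperiment")

setValidity("ArmCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"arm_id" %in% colnames(rd)) msg <- c(msg, "rowData needs 'arm_id'")
  else if (anyDuplicated(rd$arm_id)) msg <- c(msg, "arm_ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Normalized per-arm read fractions
#'
#' Same axes as \linkS4class{ArmCounts}; the \code{"fractions"} assay holds
#' each sample's per-arm read count divided by its library size, so every
#' sample (column) sums to 1.
#'
#' @seealso [normalizeToFractions()]
#' @export
setClass("ArmFractions", contains = "RangedSummarizedExperiment")

setValidity("ArmFractions", function(object) {
  msg <- character()
  if (!"fractions" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fractions' is required")
  else {
    f <- SummarizedExperiment::assay(object, "fractions")
    if (any(f < -1e-12) || any(f > 1 + 1e-12))
      msg <- c(msg, "fractions must lie in [0, 1]")
    bad <- abs(colSums(f) - 1) > 1e-9
    if (any(bad))
      msg <- c(msg, sprintf("sample fractions must sum to 1 (violated: %s)",
                            paste(colnames(f)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Healthy-control reference panel
#'
#' Holds the per-arm location (\code{armMean}) and scale (\code{armSd}) of
#' normalized read fractions across healthy controls, together with the
#' location and scale (\code{sMean}, \code{sSd}) of the genome-wide
#' sum-of-squared-Z statistic in the controls. With \code{loo = TRUE}
#' (the default when building), each control's statistic is computed
#' against a panel built from the remaining controls, removing the
#' downward bias of scoring a control against a panel containing itself.
#'
#' @slot armIds character, included arm identifiers in karyotype order.
#' @slot armMean numeric, per-arm mean control fraction (sums to 1).
#' @slot armSd numeric, per-arm control standard deviation (n-1 denominator).
#' @slot sMean,sSd numeric, location/scale of the control genome-wide
#'   statistic.
#' @slot nControls integer, number of controls used.
#' @slot loo logical, whether leave-one-out calibration was used.
#' @slot controlS numeric, the per-control genome-wide statistics the
#'   calibration was computed from.
#' @slot buildMetadata list, free-form provenance.
#' @export
setClass("ControlPanel",
  representation(armIds = "character", armMean = "numeric",
                 armSd = "numeric", sMean = "numeric", sSd = "numeric",
                 nControls = "integer", loo = "logical",
                 controlS = "numeric", buildMetadata = "list"))

setValidity("ControlPanel", function(object) {
  msg <- character()
  k <- length(object@armIds)
  if (length(object@armMean) != k || length(object@armSd) != k)
    msg <- c(msg, "armMean/armSd must match armIds in length")
  if (abs(sum(object@armMean) - 1) > 1e-9)
    msg <- c(msg, "armMean must sum to 1")
  if (any(object@armSd <= 0)) msg <- c(msg, "all armSd must be > 0")
  if (object@nControls < 3L) msg <- c(msg, "nControls must be >= 3")
  if (!is.finite(object@sSd) || object@sSd <= 0)
    msg <- c(msg, "sSd must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ControlPanel", function(object) {
  cat("ControlPanel with", length(object@armIds), "arms,",
      object@nControls, "controls",
      if (object@loo) "(leave-one-out calibrated)\n" else "(plug-in)\n")
  cat(sprintf("  genome-wide statistic: mean %.3f, sd %.3f\n",
              object@sMean, object@sSd))
})

#' Aneuploidy scoring results
#'
#' Per-sample results of the genome-wide aneuploidy score: the per-arm
#' Z-score matrix (arms x samples), the genome-wide statistic
#' \eqn{S = \sum_a z_a^2}, the score expressed in control standard
#' deviations, its dichotomization at the cut-off, and per-arm gain/loss
#' calls at the |z| threshold.
#'
#' @slot sampleIds character.
#' @slot armIds character.
#' @slot z numeric matrix, arms x samples.
#' @slot sValues numeric, genome-wide statistic per sample.
#' @slot scores numeric, aneuploidy score per sample (may be negative).
#' @slot classes factor with levels \code{low}, \code{high}.
#' @slot armCalls character matrix, arms x samples, values
#'   \code{loss}/\code{neutral}/\code{gain}.
#' @slot cutoff numeric, score dichotomization cut-off (default 5).
#' @slot zThreshold numeric, |z| threshold for arm calls (default 3).
#' @export
setClass("AneuploidyResults",
  representation(sampleIds = "character", armIds = "character",
                 z = "matrix", sValues = "numeric", scores = "numeric",
                 classes = "factor", armCalls = "matrix",
                 cutoff = "numeric", zThreshold = "numeric"))

setValidity("AneuploidyResults", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (ncol(object@z) != n || length(object@sValues) != n ||
      length(object@scores) != n || length(object@classes) != n)
    msg <- c(msg, "per-sample slots must agree in length")
  if (nrow(object@z) != length(object@armIds))
    msg <- c(msg, "z must have one row per arm")
  if (any(abs(colSums(object@z^2) - object@sValues) > 1e-9))
    msg <- c(msg, "sValues must equal column sums of z^2")
  if (!identical(levels(object@classes), c("low", "high")))
    msg <- c(msg, "classes must have levels low, high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AneuploidyResults", function(object) {
  n <- length(object@sampleIds)
  cat("AneuploidyResults for", n, "sample(s),",
      length(object@armIds), "arms\n")
  cat(sprintf("  score >= %g (high): %d/%d\n", object@cutoff,
              sum(object@classes == "high"), n))
  df <- as.data.frame(object)
  print(head(df[, c("sample_id", "s_value", "score", "score_class")], 5))
  if (n > 5) cat("  ...\n")
})

#' @describeIn AneuploidyResults-class flatten to a data.frame with one row
#'   per sample: \code{sample_id}, \code{s_value}, \code{score},
#'   \code{score_class}, then one \code{z_<arm>} column per arm.
#' @param x an \code{AneuploidyResults}.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @export
as.data.frame.AneuploidyResults <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  zt <- t(x@z)
  colnames(zt) <- paste0("z_", x@armIds)
  data.frame(sample_id = x@sampleIds, s_value = x@sValues,
             score = x@scores, score_class = as.character(x@classes),
             zt, check.names = FALSE, row.names = NULL)
}
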