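#' Per-arm Z-scores of a sample against a control panel
#'
#' \eqn{z_a = (f_a - \mu_a) / \sigma_a}, where \eqn{f_a} is the sample's
#' normalized read fraction on arm \eqn{a} and \eqn{\mu_a, \sigma_a} are
#' the control mean and standard deviation from the panel.
#'
#' @param fractions named numeric vector of per-arm fractions (names are
#'   arm identifiers; must exactly match the panel's arm set).
#' @param panel a \linkS4class{ControlPanel}.
#' @return named numeric vector of Z-scores in panel arm order.
#' @export
armZscores <- function(fractions, panel) {
  stopifnot(is(panel, "ControlPanel"))
  if (is.null(names(fractions)))
    stopf("fractions must be named by arm_id")
  d1 <- setdiff(panel@armIds, names(fractions))
  d2 <- setdiff(names(fractions), panel@armIds)
  if (length(d1) || length(d2))
    stopf("arm mismatch with panel%s%s",
          if (length(d1)) paste0("; missing: ", paste(d1, collapse = ",")) else "",
          if (length(d2)) paste0("; unexpected: ", paste(d2, collapse = ",")) else "")
  f <- fractions[panel@armIds]
  (f - panel@armMean) / panel@armSd
}

#' Genome-wide statistic: sum of squared arm Z-scores
#' @param z numeric vector of per-arm Z-scores (non-empty).
#' @return \eqn{S = \sum_a z_a^2}.
#' @export
genomeWideS <- function(z) {
  if (length(z) == 0) stopf("empty Z-score vector")
  sum(z^2)
}

#' Aneuploidy score: genome-wide statistic in control-SD units
#'
#' \eqn{(S - \mu_S) / \sigma_S} against the control distribution of the
#' genome-wide statistic; the score states by how many control standard
#' deviations a sample deviates from healthy controls. Scores below the
#' control mean are negative and reported as-is.
#'
#' @param s_value genome-wide statistic of the sample.
#' @param panel a \linkS4class{ControlPanel}.
#' @return numeric score.
#' @export
aneuploidyScore <- function(s_value, panel) {
  stopifnot(is(panel, "ControlPanel"))
  (s_value - panel@sMean) / panel@sSd
}

#' Dichotomize an aneuploidy score
#'
#' The boundary is inclusive: a score of exactly 5 is \code{high},
#' matching the established "five or higher" rule.
#'
#' @param score numeric score(s).
#' @param cutoff dichotomization cut-off (default 5).
#' @return factor with levels \code{low}, \code{high}.
#' @export
classifyScore <- function(score, cutoff = 5) {
  factor(ifelse(score >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Call per-arm gains and losses from Z-scores
#' @param z numeric vector (or arms x samples matrix) of Z-scores.
#' @param z_threshold positive |z| threshold (default 3): \code{gain} if
#'   \eqn{z \ge} threshold, \code{loss} if \eqn{z \le -}threshold, else
#'   \code{neutral}.
#' @return character vector/matrix of calls, same shape as \code{z}.
#' @export
callArmEvents <- function(z, z_threshold = 3) {
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stopf("z_threshold must be > 0")
  calls <- ifelse(z >= z_threshold, "gain",
                  ifelse(z <= -z_threshold, "loss", "neutral"))
  calls
}

#' Score samples against a control panel
#'
#' Full scoring of one or more samples: per-arm Z-scores, the genome-wide
#' statistic, the aneuploidy score, its dichotomization and per-arm
#' gain/loss calls.
#'
#' @param fractions an \linkS4class{ArmFractions} (or an
#'   \linkS4class{ArmCounts}, normalized on the fly).
#' @param panel a \linkS4class{ControlPanel}.
#' @param cutoff score dichotomization cut-off (default 5).
#' @param z_threshold arm-call threshold (default 3).
#' @return an \linkS4class{AneuploidyResults}.
#' @examples
#' ctrl <- normalizeToFractions(simulateControls(20, seed = 1))
#' panel <- buildPanel(ctrl)
#' sim <- simulateCohort(simulationConfig(n_patients = 4, seed = 2))
#' res <- scoreSamples(normalizeToFractions(sim$patients), panel)
#' aneuploidyScores(res)
#' @export
scoreSamples <- function(fractions, panel, cutoff = 5, z_threshold = 3) {
  if (is(fractions, "ArmCounts"))
    fractions <- normalizeToFractions(fractions)
  f <- fractionsMatrix(fractions)
  z <- apply(f, 2, armZscores, panel = panel)
  if (is.null(dim(z))) z <- matrix(z, ncol = ncol(f),
                                   dimnames = dimnames(f))
  s <- colSums(z^2)
  score <- aneuploidyScore(s, panel)
  new("AneuploidyResults", sampleIds = colnames(f), armIds = panel@armIds,
      z = z, sValues = unname(s), scores = unname(score),
      classes = classifyScore(unname(score), cutoff),
      armCalls = callArmEvents(z, z_threshold),
      cutoff = cutoff, zThreshold = z_threshold)
}

#' Write per-sample scoring results as TSV
#' @param results an \linkS4class{AneuploidyResults}.
#' @param path output TSV; one row per sample with score, statistic,
#'   class and per-arm Z columns.
#' @param calls_path optional second TSV mirroring the layout with
#'   gain/neutral/loss arm calls.
#' @export
writeScoresTsv <- function(results, path, calls_path = NULL) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(calls_path)) {
    cl <- t(results@armCalls)
    colnames(cl) <- paste0("call_", results@armIds)
    df <- data.frame(sample_id = results@sampleIds, cl,
                     check.names = FALSE)
    write.table(df, calls_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
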