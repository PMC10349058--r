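#' Load chromosome-arm definitions from a BED-like file
#'
#' Reads a 4-column BED file (chromosome, start, end, arm identifier;
#' 0-based half-open coordinates) and returns the arms as a
#' \linkS4class{GRanges} in karyotype order, with an \code{included} flag.
#' The acrocentric short arms 13p, 14p, 15p, 21p and 22p are flagged
#' \code{included = FALSE} (their LINE-1 content is too sparse to count),
#' and any chromosome Y entry is rejected as excluded territory.
#'
#' @param path path to a BED-like file; tab- or whitespace-separated, no
#'   header, comment lines starting with \code{#} ignored.
#' @return \linkS4class{GRanges} with metadata columns \code{arm_id}
#'   (character, unique) and \code{included} (logical).
#' @examples
#' arms <- defaultArmDefinitions()
#' sum(arms$included)  # 41
#' @export
loadArmDefinitions <- function(path) {
  if (!file.exists(path)) stopf("arm definition file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "[\t ]+")
  bad <- vapply(fields, length, 1L) < 4L
  if (any(bad))
    stopf("malformed arm definition at line %d: need 4 columns",
          lineno[which(bad)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  arm_id <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end))
    stopf("malformed arm definition at line %d: non-numeric coordinate",
          lineno[which(is.na(start) | is.na(end))[1]])
  if (any(start >= end))
    stopf("invalid arm interval at line %d: start must be < end",
          lineno[which(start >= end)[1]])
  if (anyDuplicated(arm_id))
    stopf("duplicate arm_id in definitions: %s",
          paste(unique(arm_id[duplicated(arm_id)]), collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end))
  gr$arm_id <- arm_id
  # same-chromosome arms must not overlap
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits))
    stopf("overlapping arms on one chromosome: %s / %s",
          arm_id[S4Vectors::queryHits(hits)[1]],
          arm_id[S4Vectors::subjectHits(hits)[1]])
  if (any(grepl("^(chr)?Y$", chrom, ignore.case = TRUE)))
    stopf("chromosome Y arms are excluded territory; remove them from %s",
          path)
  gr$included <- !(gr$arm_id %in% EXCLUDED_ARMS)
  gr[karyotypeOrder(gr$arm_id)]
}

#' Bundled hg19 chromosome-arm table
#'
#' Arm intervals derived from hg19 cytobands: the p arm spans from the
#' chromosome start to the centromere gap, the q arm from the gap to the
#' chromosome end (the gap itself belongs to neither arm since it carries
#' no mappable sequence). 48 arms for chromosomes 1-22 and X; the
#' canonical included set is 41 arms once the acrocentric short arms are
#' excluded. Chromosome Y is absent entirely.
#'
#' @return \linkS4class{GRanges} as from [loadArmDefinitions()].
#' @export
defaultArmDefinitions <- function() {
  loadArmDefinitions(system.file("extdata", "hg19_chromosome_arms.bed",
                                 package = "cfAneuploidy", mustWork = TRUE))
}

includedArms <- function(arms) arms[arms$included]

#' Construct an ArmCounts object
#'
#' @param counts integer matrix of raw read counts, samples in rows and
#'   included arms in columns (the on-disk orientation); it is stored
#'   internally arms x samples.
#' @param arms arm definitions from [loadArmDefinitions()]; only included
#'   arms are kept and all of them must be present as columns.
#' @return an \linkS4class{ArmCounts}.
#' @export
armCounts <- function(counts, arms = defaultArmDefinitions()) {
  inc <- includedArms(arms)
  if (is.null(colnames(counts)))
    stopf("counts needs arm_id column names")
  missing <- setdiff(inc$arm_id, colnames(counts))
  if (length(missing))
    stopf("count table is missing %d arm column(s): %s", length(missing),
          paste(missing, collapse = ", "))
  unknown <- setdiff(colnames(counts), inc$arm_id)
  if (length(unknown))
    stopf("unknown arm column(s): %s", paste(unknown, collapse = ", "))
  m <- t(counts[, inc$arm_id, drop = FALSE])
  storage.mode(m) <- "integer"
  if (is.null(colnames(m)))
    colnames(m) <- paste0("sample", seq_len(ncol(m)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), rowRanges = inc)
  new("ArmCounts", se)
}

#' Read / write a per-arm count table
#'
#' Plain TSV with a header: first column \code{sample_id}, then one
#' integer column per included arm. \code{writeCountTable} followed by
#' \code{readCountTable} round-trips exactly.
#'
#' @param path TSV file path.
#' @param arms arm definitions used to validate columns.
#' @return \code{readCountTable}: an \linkS4class{ArmCounts}.
#' @export
readCountTable <- function(path, arms = defaultArmDefinitions()) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (colnames(df)[1] != "sample_id")
    stopf("count table must start with a 'sample_id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  if (anyNA(num))
    stopf("non-numeric count cell '%s'", m[which(is.na(num))[1]])
  if (any(num != round(num)))
    stopf("non-integer count cell '%s'", m[which(num != round(num))[1]])
  cm <- matrix(as.integer(num), nrow = nrow(m), dimnames = dimnames(m))
  rownames(cm) <- df$sample_id
  armCounts(cm, arms)
}

#' @param x an \linkS4class{ArmCounts} or \linkS4class{ArmFractions}.
#' @rdname readCountTable
#' @export
writeCountTable <- function(x, path) {
  a <- SummarizedExperiment::assayNames(x)[1]
  m <- t(SummarizedExperiment::assay(x, a))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize arm counts to library-size fractions
#'
#' Each sample's per-arm read count is divided by that sample's total read
#' count over the included arms, giving the per-arm read fraction the
#' Z-scores are computed from. Fractions are invariant under uniform
#' scaling of the counts.
#'
#' @param x an \linkS4class{ArmCounts}.
#' @return an \linkS4class{ArmFractions} with the same axes.
#' @export
normalizeToFractions <- function(x) {
  stopifnot(is(x, "ArmCounts"))
  m <- SummarizedExperiment::assay(x, "counts")
  ls <- colSums(m)
  if (any(ls == 0))
    stopf("zero library size for sample(s): %s",
          paste(colnames(m)[ls == 0], collapse = ", "))
  f <- sweep(m, 2, ls, "/")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fractions = f),
    rowRanges = SummarizedExperiment::rowRanges(x))
  new("ArmFractions", se)
}

fractionsMatrix <- function(x) {
  stopifnot(is(x, "ArmFractions"))
  SummarizedExperiment::assay(x, "fractions")
}
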