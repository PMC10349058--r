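#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats sd pchisq pnorm pt qnorm cor rgamma rmultinom rbinom
#'   rexp runif rnbinom rnorm chisq.test wilcox.test cor.test setNames
#'   as.formula
#' @importFrom utils read.delim write.table head combn
NULL

# Acrocentric short arms lacking usable LINE-1 signal; always excluded
# alongside the whole of chromosome Y.
EXCLUDED_ARMS <- c("13p", "14p", "15p", "21p", "22p")

# Karyotype ordering of arm identifiers ("1p" < "1q" < "2p" < ... < "Xq").
karyotypeOrder <- function(arm_ids) {
  chrom <- sub("[pq]$", "", arm_ids)
  arm <- sub("^.*([pq])$", "\\1", arm_ids)
  chrom_num <- suppressWarnings(as.integer(chrom))
  chrom_num[chrom == "X"] <- 23L
  chrom_num[chrom == "Y"] <- 24L
  order(chrom_num, arm)
}

# Derive a stream sub-seed from a master seed, kept within 32-bit range so
# set.seed() accepts it; distinct streams decouple module-level randomness.
subSeed <- function(seed, stream) {
  ((as.numeric(seed) %% 1000003) * 2039 + as.numeric(stream) * 7919 + 1) %%
    2147483647
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Minimal htest-style container used by every statistical test in the
# package so results print uniformly and tabulate into tidy TSVs.
testResult <- function(method, statistic, p_value, n, details = list()) {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(method = method, statistic = unname(statistic),
         p.value = min(unname(p_value), 1), n = n, details = details),
    class = "cfaTest")
}

#' @export
print.cfaTest <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("  statistic = %.6g, p-value = %.4g, n = %s\n",
              x$statistic, x$p.value, paste(x$n, collapse = "/")))
  invisible(x)
}
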