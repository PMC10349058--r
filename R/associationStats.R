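#' Spearman rank correlation with t-approximation p-value
#'
#' Ties are mid-ranked; the two-sided p-value uses the t approximation
#' (exact permutation p-values are not attempted, mirroring routine
#' practice at cohort sample sizes).
#'
#' @param x,y numeric vectors of equal length (>= 3); pairs with a
#'   missing value in either are dropped, with a message.
#' @return a test result with \code{statistic} = rho.
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  if (sum(!keep) > 0)
    message(sprintf("spearmanTest: excluded %d incomplete pair(s)",
                    sum(!keep)))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("rho undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  testResult("Spearman rank correlation (t approximation)",
             ct$estimate, ct$p.value, length(x))
}

jtStatistic <- function(groups) {
  k <- length(groups)
  u <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    cmp <- outer(groups[[i]], groups[[j]], "<")
    tie <- outer(groups[[i]], groups[[j]], "==")
    u <- u + sum(cmp) + 0.5 * sum(tie)
  }
  u
}

# Tie-corrected null mean and variance of the JT statistic.
jtNullMoments <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  tj <- as.numeric(table(unlist(groups)))
  mean_u <- (N^2 - sum(n^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
         sum(n * (n - 1) * (2 * n + 5)) -
         sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(n * (n - 1) * (n - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n * (n - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  list(mean = mean_u, var = v1 + v2 + v3)
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' The statistic sums, over ordered group pairs \eqn{i < j}, the
#' Mann-Whitney counts \eqn{\#\{u < v\} + \frac{1}{2}\#\{u = v\}} for
#' \eqn{u} in group \eqn{i}, \eqn{v} in group \eqn{j}. P-values come from
#' the normal approximation with tie-corrected variance, or from a seeded
#' Monte-Carlo permutation of group labels.
#'
#' @param groups list of numeric vectors, in the hypothesized order.
#' @param alternative \code{"two.sided"} (default), \code{"increasing"}
#'   or \code{"decreasing"}.
#' @param mode \code{"normal_approx"} (default) or \code{"permutation"}.
#' @param n_perm number of permutations (permutation mode).
#' @param seed integer seed, mandatory in permutation mode so p-values
#'   are reproducible.
#' @return a test result with \code{statistic} = JT.
#' @examples
#' jonckheereTerpstra(list(c(1, 2), c(3, 4)), alternative = "increasing",
#'                    mode = "permutation", n_perm = 2000, seed = 1)
#' @export
jonckheereTerpstra <- function(groups,
                               alternative = c("two.sided", "increasing",
                                               "decreasing"),
                               mode = c("normal_approx", "permutation"),
                               n_perm = 10000, seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stopf("need at least 2 non-empty ordered groups")
  u <- jtStatistic(groups)
  N <- sum(lengths(groups))
  if (mode == "normal_approx") {
    mom <- jtNullMoments(groups)
    if (mom$var <= 0) {
      p <- 1  # all observations tied: no evidence of trend
    } else {
      zstat <- (u - mom$mean) / sqrt(mom$var)
      p <- switch(alternative,
                  two.sided = 2 * pnorm(-abs(zstat)),
                  increasing = pnorm(zstat, lower.tail = FALSE),
                  decreasing = pnorm(zstat))
      p <- min(p, 1)
    }
    testResult("Jonckheere-Terpstra trend test (normal approximation)",
               u, p, N, details = list(alternative = alternative))
  } else {
    if (is.null(seed))
      stopf("permutation mode requires a seed for reproducibility")
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    idx_end <- cumsum(sizes)
    idx_start <- c(1, head(idx_end, -1) + 1)
    perm_u <- withSeed(seed, vapply(seq_len(n_perm), function(b) {
      shuffled <- sample(pooled)
      jtStatistic(lapply(seq_along(sizes), function(g)
        shuffled[idx_start[g]:idx_end[g]]))
    }, numeric(1)))
    mom <- jtNullMoments(groups)
    p <- switch(alternative,
                increasing = (1 + sum(perm_u >= u)) / (n_perm + 1),
                decreasing = (1 + sum(perm_u <= u)) / (n_perm + 1),
                two.sided = (1 + sum(abs(perm_u - mom$mean) >=
                                       abs(u - mom$mean))) / (n_perm + 1))
    testResult("Jonckheere-Terpstra trend test (permutation)",
               u, p, N,
               details = list(alternative = alternative,
                              n_perm = n_perm, seed = seed))
  }
}

#' Mann-Whitney U test
#'
#' U counts pairs where an \code{x} observation exceeds a \code{y}
#' observation (ties contribute one half), the orientation of
#' \code{stats::wilcox.test}; \code{x} entirely below \code{y} therefore
#' gives U = 0. The p-value is by exact enumeration when both samples
#' have at most 8 observations and no ties, otherwise by the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (non-empty; NAs dropped).
#' @param alternative as in \code{wilcox.test}.
#' @return a test result with \code{statistic} = U.
#' @export
mannWhitneyTest <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = use_exact, correct = TRUE))
  testResult(paste0("Mann-Whitney U test (",
                    if (use_exact) "exact" else "normal approximation",
                    ")"),
             wt$statistic, wt$p.value, c(length(x), length(y)),
             details = list(alternative = alternative, exact = use_exact))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No Yates continuity correction by default (cohort-sized tables).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correction apply Yates correction (default \code{FALSE}).
#' @return a test result, df = 1.
#' @export
chiSquare2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("need a 2x2 table")
  if (any(table < 0) || any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("all margins must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = correction))
  testResult("Pearson chi-square test (2x2)", ct$statistic, ct$p.value,
             sum(table), details = list(df = 1, yates = correction))
}

#' Cross-tabulate dichotomized aneuploidy score and CTC count
#'
#' Both markers dichotomize at an inclusive cut-off of 5: a sample with
#' score exactly 5 and CTC count exactly 5 lands in the high/high cell.
#'
#' @param scores numeric aneuploidy scores.
#' @param ctcs CTC counts per 7.5 mL blood.
#' @param cutoff shared cut-off (default 5).
#' @return list of class \code{concordanceTable} with cells
#'   \code{n_low_low}, \code{n_high_high}, \code{n_ctc_only_high},
#'   \code{n_score_only_high} and the \code{total}.
#' @export
crossTabulate <- function(scores, ctcs, cutoff = 5) {
  if (length(scores) != length(ctcs)) stopf("length mismatch")
  if (anyNA(scores) || anyNA(ctcs))
    stopf("missing values must be filtered before cross-tabulation")
  score_high <- scores >= cutoff
  ctc_high <- ctcs >= cutoff
  structure(list(
    n_low_low = sum(!score_high & !ctc_high),
    n_high_high = sum(score_high & ctc_high),
    n_ctc_only_high = sum(!score_high & ctc_high),
    n_score_only_high = sum(score_high & !ctc_high),
    total = length(scores)), class = "concordanceTable")
}

#' @export
print.concordanceTable <- function(x, ...) {
  cat("Concordance of dichotomized aneuploidy score vs CTC count\n")
  pct <- function(n) sprintf("%d (%.1f%%)", n, 100 * n / x$total)
  cat("  both low:       ", pct(x$n_low_low), "\n")
  cat("  both high:      ", pct(x$n_high_high), "\n")
  cat("  CTC high only:  ", pct(x$n_ctc_only_high), "\n")
  cat("  score high only:", pct(x$n_score_only_high), "\n")
  cat(sprintf("  discordance: %.1f%%\n", discordanceRate(x)))
  invisible(x)
}

#' Assemble a concordance table from the four cell counts
#' @param n_low_low,n_high_high,n_ctc_only_high,n_score_only_high
#'   non-negative cell counts.
#' @return a \code{concordanceTable}.
#' @export
concordanceTable <- function(n_low_low, n_high_high, n_ctc_only_high,
                             n_score_only_high) {
  cells <- c(n_low_low, n_high_high, n_ctc_only_high, n_score_only_high)
  if (any(cells < 0) || sum(cells) == 0)
    stopf("cells must be non-negative with positive total")
  structure(list(n_low_low = n_low_low, n_high_high = n_high_high,
                 n_ctc_only_high = n_ctc_only_high,
                 n_score_only_high = n_score_only_high,
                 total = sum(cells)), class = "concordanceTable")
}

#' Discordance rate of a concordance table
#' @param table a \code{concordanceTable}.
#' @return percentage of samples high on exactly one marker, rounded to
#'   one decimal.
#' @export
discordanceRate <- function(table) {
  stopifnot(inherits(table, "concordanceTable"))
  if (table$total == 0) stopf("empty table")
  round(100 * (table$n_ctc_only_high + table$n_score_only_high) /
          table$total, 1)
}

#' 2x2 matrix view of a concordance table (rows: score, cols: CTC)
#' @param table a \code{concordanceTable}.
#' @return 2x2 integer matrix suitable for [chiSquare2x2()].
#' @export
concordanceMatrix <- function(table) {
  matrix(c(table$n_low_low, table$n_ctc_only_high,
           table$n_score_only_high, table$n_high_high),
         2, 2, byrow = TRUE,
         dimnames = list(score = c("low", "high"),
                         ctc = c("low", "high")))
}
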