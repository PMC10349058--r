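# Fixtures are built in code at test time; nothing binary ships with the
# package.

SAM_HEADER <- c(
  "@HD\tVN:1.6\tSO:unsorted",
  "@SQ\tSN:chr1\tLN:249250621",
  "@SQ\tSN:chr13\tLN:115169878")

samRead <- function(qname, flag, rname, pos, mapq = 60) {
  paste(qname, flag, rname, format(pos, scientific = FALSE), mapq, "4M",
        "*", 0, 0, "ACGT", "IIII", sep = "\t")
}

writeSam <- function(reads, path = tempfile(fileext = ".sam")) {
  writeLines(c(SAM_HEADER, reads), path)
  path
}

# three-arm toy definitions on one chromosome
writeToyArms <- function(path = tempfile(fileext = ".bed")) {
  writeLines(c("chr1\t0\t1000\t1p",
               "chr1\t2000\t3000\t1q",
               "chr2\t0\t1000\t2p"), path)
  path
}

# ArmFractions straight from a samples x arms fraction matrix on toy arms
toyFractions <- function(fr, arm_bed = writeToyArms()) {
  arms <- loadArmDefinitions(arm_bed)
  counts <- round(fr * 1e6)
  dimnames(counts) <- list(paste0("s", seq_len(nrow(fr))), arms$arm_id)
  armCounts(counts, arms) |> normalizeToFractions()
}

# independent product-limit estimator: explicit loop over risk sets
oracleKm <- function(time, event) {
  etimes <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(etimes))
  for (i in seq_along(etimes)) {
    t <- etimes[i]
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    s <- s * (1 - d_t / n_t)
    surv[i] <- s
  }
  data.frame(time = etimes, survival = surv)
}

# independent two-group log-rank chi-square via risk-table arithmetic
oracleLogrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  etimes <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in etimes) {
    at <- time >= t
    n <- sum(at); d <- sum(time == t & event == 1)
    n1 <- sum(at & group == g[1])
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exhaustive JT null distribution by enumerating all group labelings
oracleJtExact <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  idx <- utils::combn(N, sizes[1], simplify = FALSE)
  stopifnot(length(sizes) == 2)  # oracle written for two groups
  vapply(idx, function(i) {
    cfAneuploidy:::jtStatistic(list(pooled[i], pooled[-i]))
  }, numeric(1))
}

# exact Mann-Whitney two-sided p by enumerating assignments
oracleMwExactP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- vapply(utils::combn(length(pooled), nx, simplify = FALSE),
               function(i) {
                 xi <- pooled[i]; yi <- pooled[-i]
                 sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
               }, numeric(1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
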