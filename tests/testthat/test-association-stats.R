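test_that("spearman handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(unname(spearmanTest(x, exp(x))$statistic), 1)
  expect_equal(unname(spearmanTest(x, rev(x))$statistic), -1)
  # tie: rho equals Pearson on midranks
  y <- c(2, 2, 5, 1, 7, 6)
  rho <- spearmanTest(x, y)$statistic
  expect_equal(unname(rho), cor(rank(x), rank(y)))
  expect_error(spearmanTest(x, rep(1, 6)), "constant")
})

test_that("JT statistic and exact null match exhaustive enumeration", {
  g <- list(c(1, 2), c(3, 4))
  res <- jonckheereTerpstra(g, alternative = "increasing")
  expect_equal(res$statistic, 4)
  null_u <- oracleJtExact(g)
  expect_equal(mean(null_u >= 4), 1 / 6)
  perm <- jonckheereTerpstra(g, alternative = "increasing",
                             mode = "permutation", n_perm = 6000,
                             seed = 42)
  expect_lt(abs(perm$p.value - 1 / 6), 0.02)
})

test_that("JT with constant data reports no trend", {
  res <- jonckheereTerpstra(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_gt(res$p.value, 0.99)
})

test_that("JT normal approximation agrees with permutation", {
  set.seed(10)
  g <- list(rnorm(4, 0), rnorm(4, 0.8), rnorm(4, 1.6))
  pn <- jonckheereTerpstra(g, alternative = "increasing")$p.value
  pp <- jonckheereTerpstra(g, alternative = "increasing",
                           mode = "permutation", n_perm = 20000,
                           seed = 99)$p.value
  expect_lt(abs(pn - pp), 0.02)
})

test_that("two-group JT matches the Mann-Whitney one-sided p", {
  set.seed(11)
  a <- rnorm(7); b <- rnorm(9, 0.5)
  jt <- jonckheereTerpstra(list(a, b), alternative = "increasing")
  # JT counts pairs a < b, i.e. evidence y tends larger: MW "less"
  mw <- suppressWarnings(stats::wilcox.test(a, b, alternative = "less",
                                            exact = FALSE,
                                            correct = FALSE))
  expect_equal(jt$p.value, mw$p.value, tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and bounded", {
  g <- list(c(1, 3, 2), c(2, 4, 5), c(5, 6, 7))
  p1 <- jonckheereTerpstra(g, mode = "permutation", n_perm = 500,
                           seed = 7)$p.value
  p2 <- jonckheereTerpstra(g, mode = "permutation", n_perm = 500,
                           seed = 7)$p.value
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 501)
  expect_error(jonckheereTerpstra(g, mode = "permutation"), "seed")
})

test_that("Mann-Whitney orientation, null and exact enumeration", {
  res <- mannWhitneyTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res$statistic), 0)
  same <- mannWhitneyTest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p.value, 0.85)
  set.seed(12)
  x <- rnorm(5); y <- rnorm(5, 1)
  expect_equal(mannWhitneyTest(x, y)$p.value, oracleMwExactP(x, y),
               tolerance = 1e-9)
  expect_error(mannWhitneyTest(numeric(), 1), "non-empty")
})

test_that("chi-square matches direct O/E arithmetic", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_lt(chiSquare2x2(prop)$statistic, 1e-9)
  expect_equal(chiSquare2x2(prop)$p.value, 1)

  set.seed(13)
  tab <- matrix(rpois(4, 30) + 1, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(chiSquare2x2(tab)$statistic),
               sum((tab - E)^2 / E))
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("score/CTC association is significant on the published table", {
  conc <- concordanceTable(73, 46, 34, 21)
  res <- chiSquare2x2(concordanceMatrix(conc))
  expect_lt(res$p.value, 0.001)
})

test_that("cross-tabulation cells and boundary inclusivity", {
  ct <- crossTabulate(c(4, 6, 4, 9), c(4, 6, 9, 4))
  expect_equal(ct$n_low_low, 1)
  expect_equal(ct$n_high_high, 1)
  expect_equal(ct$n_ctc_only_high, 1)
  expect_equal(ct$n_score_only_high, 1)
  expect_equal(crossTabulate(5, 5)$n_high_high, 1)
  only_low <- crossTabulate(c(1, 2), c(0, 3))
  expect_equal(only_low$n_low_low, 2)
  expect_error(crossTabulate(1:3, 1:2), "mismatch")
})

test_that("discordance rate reproduces the worked example", {
  expect_equal(discordanceRate(concordanceTable(73, 46, 34, 21)), 31.6)
  expect_equal(discordanceRate(concordanceTable(10, 10, 0, 0)), 0)
  expect_equal(discordanceRate(concordanceTable(0, 0, 1, 1)), 100)
})
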