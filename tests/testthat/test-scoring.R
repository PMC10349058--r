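toyPanel <- function(mu = c(0.25, 0.30, 0.45), sdev = c(0.025, 0.05, 0.05),
                     s_mean = 40, s_sd = 8) {
  new("ControlPanel", armIds = c("1p", "1q", "2p"), armMean = mu,
      armSd = sdev, sMean = s_mean, sSd = s_sd, nControls = 10L,
      loo = TRUE, controlS = numeric(), buildMetadata = list())
}

test_that("arm Z-scores center and scale against the panel", {
  panel <- toyPanel()
  f <- c("1p" = 0.25, "1q" = 0.30, "2p" = 0.45)
  expect_equal(unname(armZscores(f, panel)), c(0, 0, 0))
  f2 <- c("1p" = 0.30, "1q" = 0.30, "2p" = 0.40)
  z <- armZscores(f2, panel)
  expect_equal(unname(z["1p"]), 2.0)
  # antisymmetry
  f3 <- c("1p" = 0.20, "1q" = 0.30, "2p" = 0.50)
  expect_equal(unname(armZscores(f3, panel)["1p"]), -2.0)
  expect_error(armZscores(c("1p" = 0.5, "8q" = 0.5), panel),
               "arm mismatch")
})

test_that("genome-wide statistic is the sum of squared Z-scores", {
  expect_equal(genomeWideS(rep(0, 41)), 0)
  expect_equal(genomeWideS(c(3, -4)), 25)
  set.seed(8)
  z <- rnorm(41)
  brute <- 0
  for (v in z) brute <- brute + v * v
  expect_equal(genomeWideS(z), brute)
  expect_error(genomeWideS(numeric()), "empty")
})

test_that("aneuploidy score is S in control-SD units", {
  panel <- toyPanel(s_mean = 40, s_sd = 8)
  expect_equal(aneuploidyScore(40, panel), 0)
  expect_equal(aneuploidyScore(40 + 5 * 8, panel), 5)
  expect_equal(classifyScore(aneuploidyScore(80, panel)), factor("high", c("low", "high")))
  expect_equal(aneuploidyScore(100, panel), 7.5)
})

test_that("classification boundary is inclusive at the cut-off", {
  expect_equal(as.character(classifyScore(c(4.999, 5, -2.3))),
               c("low", "high", "low"))
})

test_that("arm events call gains and losses at the |z| threshold", {
  expect_equal(callArmEvents(c(3.5, -3.5, 1.0, 3.0, -3.0)),
               c("gain", "loss", "neutral", "gain", "loss"))
  expect_equal(unique(callArmEvents(rep(0, 41))), "neutral")
  expect_error(callArmEvents(1, z_threshold = 0), "z_threshold")
})

# single-pass brute-force scorer, independent of the pipeline path
oracleScore <- function(fraction_vec, panel) {
  s <- 0
  for (a in panel@armIds) {
    mu <- panel@armMean[match(a, panel@armIds)]
    sdv <- panel@armSd[match(a, panel@armIds)]
    s <- s + ((fraction_vec[a] - mu) / sdv)^2
  }
  (s - panel@sMean) / panel@sSd
}

test_that("pipeline score equals the brute-force oracle", {
  ctrl <- normalizeToFractions(simulateControls(15, seed = 2))
  panel <- buildPanel(ctrl)
  cfg <- simulationConfig(n_patients = 20, seed = 13)
  sim <- simulateCohort(cfg)
  fr <- normalizeToFractions(sim$patients)
  res <- scoreSamples(fr, panel)
  f <- SummarizedExperiment::assay(fr, "fractions")
  for (i in seq_len(ncol(f)))
    expect_equal(unname(aneuploidyScores(res)[i]),
                 unname(oracleScore(f[, i], panel)), tolerance = 1e-12)
})

test_that("score is invariant to library-size rescaling of counts", {
  ctrl <- normalizeToFractions(simulateControls(10, seed = 4))
  panel <- buildPanel(ctrl)
  cfg <- simulationConfig(n_patients = 3, seed = 6)
  sim <- simulateCohort(cfg)
  m <- SummarizedExperiment::assay(sim$patients, "counts")
  x1 <- armCounts(t(m), cfg$arms)
  x2 <- armCounts(t(m * 3L), cfg$arms)
  expect_equal(aneuploidyScores(scoreSamples(x1, panel)),
               aneuploidyScores(scoreSamples(x2, panel)))
})

test_that("default CN profile enriches the canonical gains and losses", {
  ctrl <- normalizeToFractions(simulateControls(20, seed = 21))
  panel <- buildPanel(ctrl)
  p <- baselineArmWeights()
  q <- expectedFractions(p, defaultCNProfile(), tf = 0.3)
  set.seed(22)
  calls <- replicate(40, {
    cts <- simulateCounts(q, 90000, 50000)
    z <- armZscores(cts / sum(cts), panel)
    callArmEvents(z)
  })
  gain_freq <- rowMeans(calls == "gain")
  loss_freq <- rowMeans(calls == "loss")
  names(gain_freq) <- names(loss_freq) <- panel@armIds
  # the profiled alterations are the most frequently called arms
  expect_setequal(names(sort(gain_freq, decreasing = TRUE))[1:2],
                  c("1q", "8q"))
  expect_setequal(names(sort(loss_freq, decreasing = TRUE))[1:4],
                  c("8p", "10q", "13q", "17p"))
  neutral <- setdiff(panel@armIds, c("1q", "8q", "8p", "10q", "13q", "17p"))
  expect_lt(max(gain_freq[neutral], loss_freq[neutral]), 0.5)
})
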