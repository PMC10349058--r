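test_that("bundled arm table has the canonical included set", {
  arms <- defaultArmDefinitions()
  expect_equal(length(arms), 46)
  expect_equal(sum(arms$included), 41)
  expect_setequal(arms$arm_id[!arms$included],
                  c("13p", "14p", "15p", "21p", "22p"))
  expect_false(any(grepl("Y", as.character(GenomicRanges::seqnames(arms)))))
  # karyotype order
  expect_equal(arms$arm_id[1:4], c("1p", "1q", "2p", "2q"))
  expect_equal(arms$arm_id[45:46], c("Xp", "Xq"))
})

test_that("arm definition parsing validates structure", {
  toy <- writeToyArms()
  arms <- loadArmDefinitions(toy)
  expect_equal(arms$arm_id, c("1p", "1q", "2p"))
  expect_true(all(arms$included))
  expect_equal(GenomicRanges::start(arms), c(1, 2001, 1))
  expect_equal(GenomicRanges::end(arms), c(1000, 3000, 1000))

  dup <- tempfile(); writeLines(c("chr1\t0\t10\t1p", "chr1\t20\t30\t1p"), dup)
  expect_error(loadArmDefinitions(dup), "duplicate arm_id")

  ovl <- tempfile(); writeLines(c("chr1\t0\t100\t1p", "chr1\t50\t200\t1q"), ovl)
  expect_error(loadArmDefinitions(ovl), "overlapping")

  bad <- tempfile(); writeLines(c("chr1\t0\t100\t1p", "chr1\t50"), bad)
  expect_error(loadArmDefinitions(bad), "line 2")

  y <- tempfile(); writeLines("chrY\t0\t100\tYp", y)
  expect_error(loadArmDefinitions(y), "Y")
})

test_that("count tables round-trip and reject malformed cells", {
  arms <- defaultArmDefinitions()
  set.seed(1)
  m <- matrix(rpois(2 * 41, 2000), nrow = 2,
              dimnames = list(c("s1", "s2"),
                              arms$arm_id[arms$included]))
  x <- armCounts(m, arms)
  path <- tempfile(fileext = ".tsv")
  writeCountTable(x, path)
  y <- readCountTable(path, arms)
  expect_identical(SummarizedExperiment::assay(y, "counts"),
                   SummarizedExperiment::assay(x, "counts"))

  txt <- readLines(path)
  txt[2] <- sub("\t\\d+$", "\t3.5", txt[2])
  bad <- tempfile(); writeLines(txt, bad)
  expect_error(readCountTable(bad, arms), "non-integer")

  toy <- loadArmDefinitions(writeToyArms())
  m3 <- matrix(1:6, 2, dimnames = list(c("a", "b"), c("1p", "1q", "2p")))
  p3 <- tempfile(); writeCountTable(armCounts(m3, toy), p3)
  expect_error(readCountTable(p3, arms), "missing.*arm")
})

test_that("normalization divides by library size and is scale invariant", {
  toy <- loadArmDefinitions(writeToyArms())
  m <- matrix(c(10, 30, 60), 1, dimnames = list("s", c("1p", "1q", "2p")))
  fr <- normalizeToFractions(armCounts(m, toy))
  expect_equal(unname(SummarizedExperiment::assay(fr, "fractions")[, 1]),
               c(0.1, 0.3, 0.6))

  arms <- defaultArmDefinitions()
  eq <- matrix(100L, 1, 41,
               dimnames = list("s", arms$arm_id[arms$included]))
  fru <- normalizeToFractions(armCounts(eq, arms))
  expect_equal(unname(SummarizedExperiment::assay(fru, "fractions")[, 1]),
               rep(1 / 41, 41))

  fr2 <- normalizeToFractions(armCounts(m * 7L, toy))
  expect_equal(SummarizedExperiment::assay(fr2, "fractions"),
               SummarizedExperiment::assay(fr, "fractions"))

  z <- matrix(0L, 1, 3, dimnames = list("empty", c("1p", "1q", "2p")))
  expect_error(normalizeToFractions(armCounts(z, toy)), "empty")
})

test_that("fractions row-sum to 1 for random count tables", {
  arms <- defaultArmDefinitions()
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rpois(3 * 41, 50 * i) + 1L, nrow = 3,
                dimnames = list(paste0("s", 1:3),
                                arms$arm_id[arms$included]))
    fr <- normalizeToFractions(armCounts(m, arms))
    expect_true(all(abs(colSums(
      SummarizedExperiment::assay(fr, "fractions")) - 1) < 1e-9))
  }
})
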