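test_that("segmentDeviation subtracts the overall mean per segment", {
  vals <- matrix(c(1, 2, 3), 1, 3)           # one segment, three cells
  prof <- makeProfile(vals, "1", c("reference", "observation", "observation"))
  dev <- segmentDeviation(prof)
  expect_equal(as.numeric(dev), c(-1, 0, 1))

  # identical cells -> all deviations zero; column means always zero
  profe <- makeProfile(matrix(4, 3, 5), rep("1", 3),
                       rep(c("reference", "observation"), c(2, 3)))
  expect_true(all(segmentDeviation(profe) == 0))
  set.seed(1)
  profr <- randomProfile(8, 2, 5)
  expect_lt(max(abs(colMeans(segmentDeviation(profr)))), 1e-12)

  single <- makeProfile(matrix(1, 2, 1), c("1", "1"), "observation")
  expect_error(segmentDeviation(single), "2 cells")
})

test_that("chromosomeDeviationSum is the signed per-chromosome sum", {
  dev <- matrix(c(0.2, -0.1, 0.4), 1, 3)
  D <- chromosomeDeviationSum(dev, c("1", "1", "1"))
  expect_equal(as.numeric(D), 0.5)

  zero <- chromosomeDeviationSum(matrix(0, 4, 6), rep(c("1", "2"), 3))
  expect_true(all(zero == 0))

  # centering means per-chromosome column sums over cells vanish
  set.seed(2)
  prof <- randomProfile(12, 3, 4)
  D2 <- chromosomeDeviationSum(segmentDeviation(prof),
                               segmentChromosomes(prof))
  expect_lt(max(abs(colSums(D2))), 1e-10)

  expect_error(chromosomeDeviationSum(dev, c("1", NA, "1")),
               "without a chromosome")
  expect_error(chromosomeDeviationSum(dev, c("1", "1")), "per segment")
})

test_that("findPeak locates the mode, with median fallback", {
  expect_equal(findPeak(3.7), 3.7)                 # single value
  expect_equal(findPeak(rep(2, 50)), 2)            # degenerate sample
  set.seed(11)
  x <- c(rnorm(900, 0, 0.1), rnorm(100, 5, 0.1))   # 90% cluster at 0
  expect_lt(abs(findPeak(x)), 0.2)
  set.seed(12)
  y <- rnorm(1000)
  expect_lt(abs(findPeak(y)), 0.15)
  expect_error(findPeak(numeric(0)), "non-empty")
  expect_error(findPeak(c(1, NA)), "finite")
})

test_that("callOutliers applies the strict multiplier-SD rule", {
  expect_false(any(callOutliers(rep(1, 6), peak = 1)))   # zero SD
  v <- c(0, 0, 0, 0, 10)
  pk <- findPeak(v)                                       # median fallback: 0
  got <- callOutliers(v, pk, multiplier = 2.0)
  expect_identical(got, abs(v - pk) > 2.0 * sd(v))
  # a value exactly at peak + m*s is not flagged (strict inequality):
  # v = {0,0,0,10}, median peak 0, sd 5, multiplier 2 -> threshold 10
  v2 <- c(0, 0, 0, 10)
  expect_false(any(callOutliers(v2, findPeak(v2), multiplier = 2)))
  expect_error(callOutliers(c(1, Inf), 0), "finite")
  expect_error(callOutliers(1, 0), "length >= 2")
})

test_that("aneuploidCall counts flagged cells per group", {
  D <- matrix(rnorm(20), 10, 2)
  flags <- matrix(FALSE, 10, 2, dimnames = list(paste0("c", 1:10),
                                                c("1", "2")))
  flags[c(1, 5), 1] <- TRUE
  flags[c(5, 9), 2] <- TRUE
  rownames(D) <- rownames(flags); colnames(D) <- colnames(flags)
  tab <- new("DeviationTable", D = D, peak = c(0, 0), sd = c(1, 1),
             outlier = flags, cellGroup = rep("observation", 10),
             multiplier = 2.5)
  call <- aneuploidCall(tab, "observation")
  expect_equal(aneuploidFraction(call), 0.3)
  expect_identical(flaggedChromosomes(call)$c5, c("1", "2"))
  expect_identical(flaggedChromosomes(call)$c2, character(0))
  # no flags anywhere -> fraction 0
  tab0 <- new("DeviationTable", D = D, peak = c(0, 0), sd = c(1, 1),
              outlier = flags & FALSE, cellGroup = rep("observation", 10),
              multiplier = 2.5)
  expect_equal(aneuploidFraction(aneuploidCall(tab0)), 0)
  expect_error(aneuploidCall(tab, "reference"), "no cells in group")

  # random flag matrices: fraction equals a brute-force row count
  set.seed(4)
  for (rep in 1:10) {
    fl <- matrix(runif(30) < 0.3, 10, 3,
                 dimnames = list(paste0("c", 1:10), c("1", "2", "3")))
    grp <- sample(c("reference", "observation"), 10, replace = TRUE)
    if (!any(grp == "observation")) grp[1] <- "observation"
    tabr <- new("DeviationTable", D = matrix(0, 10, 3, dimnames = dimnames(fl)),
                peak = c(0, 0, 0), sd = c(1, 1, 1), outlier = fl,
                cellGroup = grp, multiplier = 2.5)
    manual <- sum(apply(fl, 1, any) & grp == "observation") /
      sum(grp == "observation")
    expect_equal(aneuploidFraction(aneuploidCall(tabr)), manual)
  }
})

test_that("scoring pipeline matches the straight-line brute force", {
  set.seed(99)
  for (i in 1:25) {
    nCells <- sample(4:20, 1)
    segPer <- sample(3:12, 1)
    prof <- randomProfile(nCells, 3, segPer, nRef = max(2, nCells %/% 2))
    for (sdOver in c("reference", "all")) {
      res <- scoreAneuploidy(prof, sdOver = sdOver)
      bf <- bruteForceScore(cnvValues(prof), segmentChromosomes(prof),
                            cellGroups(prof), sdOver = sdOver)
      expect_lt(max(abs(deviations(res$table) - bf$D)), 1e-10)
      expect_lt(max(abs(peakValues(res$table) - bf$peak)), 1e-10)
      expect_lt(max(abs(sdValues(res$table) - bf$sd)), 1e-10)
      expect_identical(unname(outlierFlags(res$table)), unname(bf$flags))
      expect_equal(aneuploidFraction(res$call), bf$fraction)
    }
  }
})

test_that("scoring is invariant to translating a segment across all cells", {
  set.seed(21)
  prof <- randomProfile(15, 2, 6)
  shifted <- prof
  x <- cnvValues(prof)
  x[4, ] <- x[4, ] + 7.3
  SummarizedExperiment::assay(shifted, "cnv") <- x
  a <- scoreAneuploidy(prof)
  b <- scoreAneuploidy(shifted)
  expect_equal(deviations(a$table), deviations(b$table))
  expect_identical(outlierFlags(a$table), outlierFlags(b$table))
  expect_equal(aneuploidFraction(a$call), aneuploidFraction(b$call))
})
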