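test_that("methylation level is the intensity ratio of the peak pair", {
  expect_identical(methylationLevel(500, 500), 0.5)
  expect_identical(methylationLevel(812, 0), 1)
  expect_identical(methylationLevel(0, 812), 0)
  expect_identical(methylationLevel(300, 100), 0.75)
})

test_that("a both-zero or missing pair yields an absent level, never 0/0", {
  expect_true(is.na(methylationLevel(0, 0)))
  expect_true(is.na(methylationLevel(NA, NA)))
  expect_error(methylationLevel(-1, 5), "nonnegative")
})

test_that("complementary pairs sum to one and the ratio is scale-invariant", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0, 5000); b <- runif(1, 0, 5000)
    expect_equal(methylationLevel(a, b) + methylationLevel(b, a), 1)
    k <- runif(1, 0.01, 100)
    expect_equal(methylationLevel(k * a, k * b), methylationLevel(a, b))
  }
})

test_that("homogeneity test matches the textbook pooled t to 10 digits", {
  # fixed hand-checkable case: df = 2
  res <- conversionHomogeneityTest(c(0.2, 0.4), c(0.6, 0.8))
  oracle <- pooledTOracle(c(0.2, 0.4), c(0.6, 0.8))
  expect_equal(res$df, 2L)
  expect_true(agreesTo(res$t_statistic, oracle$t, 10))
  expect_true(agreesTo(res$p_value, oracle$p, 10))

  set.seed(7)
  for (i in 1:25) {
    x <- runif(sample(2:8, 1)); y <- runif(sample(2:8, 1))
    res <- conversionHomogeneityTest(x, y)
    oracle <- pooledTOracle(x, y)
    expect_true(agreesTo(res$t_statistic, oracle$t, 10))
    expect_true(agreesTo(res$p_value, oracle$p, 10))
    expect_equal(res$df, oracle$df)
  }
})

test_that("homogeneity test handles degenerate and undersized groups", {
  res <- conversionHomogeneityTest(c(0.4, 0.5), c(0.4, 0.5))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$passed)

  # zero pooled variance, equal means
  res <- conversionHomogeneityTest(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)

  # zero pooled variance, unequal means: degenerate certain rejection
  res <- conversionHomogeneityTest(c(0.3, 0.3), c(0.5, 0.5))
  expect_equal(res$p_value, 0)
  expect_true(res$degenerate)
  expect_false(res$passed)

  expect_error(conversionHomogeneityTest(0.5, c(0.4, 0.6)),
               "insufficient replicates")
})

test_that("replicate averaging is the per-locus mean over present values", {
  reps <- data.frame(sample_id = "s1", conversion = c(1, 1, 2, 2),
                     amplification = c(1, 2, 1, 2), locus = "ELOVL2",
                     level = rep(0.6, 4))
  expect_equal(averageReplicates(reps)$ELOVL2, 0.6)

  reps$locus <- "FHL2"; reps$level <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(averageReplicates(reps)$FHL2, 0.5)

  # locus present in only 2 of 4 replicates: mean over the present ones
  reps$locus <- "KLF14"; reps$level <- c(0.3, NA, 0.5, NA)
  avg <- averageReplicates(reps)
  expect_equal(avg$KLF14, 0.4)
  expect_true(is.na(avg$ELOVL2))  # absent everywhere stays absent
})

test_that("replicate averaging is permutation-invariant and idempotent", {
  set.seed(11)
  reps <- expand.grid(conversion = 1:2, amplification = 1:2,
                      locus = locusOrder(), stringsAsFactors = FALSE)
  reps$sample_id <- "s1"
  reps$level <- runif(nrow(reps))
  base <- averageReplicates(reps)
  shuffled <- reps[sample(nrow(reps)), ]
  expect_equal(averageReplicates(shuffled), base)

  # averaging an already-averaged single profile changes nothing
  single <- data.frame(sample_id = "s1", conversion = 1, amplification = 1,
                       locus = locusOrder(),
                       level = as.numeric(base[1, locusOrder()]))
  expect_equal(averageReplicates(single), base)
})

test_that("control checks enforce high/low bounds per locus", {
  m <- profileOf(rep(0.97, 5))
  u <- profileOf(rep(0.03, 5))
  res <- checkControls(m, u, lowBound = 0.1, highBound = 0.9)
  expect_true(res$batchPassed)
  expect_true(all(res$checks$passed))

  m["ELOVL2"] <- 0.7
  res <- checkControls(m, u)
  expect_false(res$batchPassed)
  bad <- res$checks[res$checks$locus == "ELOVL2" &
                    res$checks$control_type == "methylated", ]
  expect_false(bad$passed)

  u2 <- u[setdiff(locusOrder(), "TRIM59")]
  expect_warning(res <- checkControls(profileOf(rep(0.97, 5)), u2),
                 "TRIM59")
  unev <- res$checks[res$checks$locus == "TRIM59" &
                     res$checks$control_type == "unmethylated", ]
  expect_true(is.na(unev$passed))
})

test_that("cohort-level homogeneity pools amplifications within conversions", {
  cfg <- syntheticConfig(nSamples = 8, seed = 21)
  pk <- generatePeakTable(generateCohort(cfg), cfg, includeControls = FALSE)
  lv <- quantifyPeakTable(pk)
  hom <- cohortHomogeneity(lv)
  expect_setequal(hom$locus, locusOrder())
  # per locus: 8 samples x 2 amplifications per conversion batch
  expect_true(all(hom$df == 2 * 8 * 2 - 2))
  expect_true(all(hom$p_value >= 0 & hom$p_value <= 1))

  perS <- cohortHomogeneity(lv, perSample = TRUE)
  expect_equal(nrow(perS), 8 * 5)
  expect_true(all(perS$df == 2L))
})

test_that("quantifyPeakTable turns peak groups into tidy levels", {
  pk <- rbind(
    peakRows("ELOVL2", c("C", "T"), c(300, 100)),
    peakRows("KLF14", "G", 500),
    peakRows("FHL2", c("C", "T"), c(200, 600), conversion = 2L)
  )
  lv <- quantifyPeakTable(pk)
  expect_equal(nrow(lv), 3L)
  expect_equal(lv$level[lv$locus == "ELOVL2"], 0.75)
  expect_equal(lv$level[lv$locus == "KLF14"], 1)
  expect_equal(lv$level[lv$locus == "FHL2"], 0.25)

  # a minimum-height threshold drops subthreshold peaks before pairing
  lv <- quantifyPeakTable(pk, minHeight = 150)
  expect_equal(lv$level[lv$locus == "ELOVL2"], 1)
})
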