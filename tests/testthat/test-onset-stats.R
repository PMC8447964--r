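mkMpr <- function(times, values, ids) {
  new("MPRSeries", windowTimes = times, segmentIds = ids, mpr = values,
      normalizedMpr = rep(NA_real_, length(values)),
      bands = BandDefinition(), baselineMedian = NA_real_)
}

test_that("baseline pools windows at or before the 900-s cutoff", {
  m <- mkMpr(c(-300, 600, 1200, 1800), c(1, 3, 2, 100),
             c("a", "b", "c", "d"))
  b <- baselineMedian(m)
  expect_equal(b$baselineMedianMpr, 2)    # median of 1, 3
  expect_equal(b$nBaselineWindows, 2)
  # segments at -5, 10, 20 min: only the first two are baseline
  m2 <- mkMpr(c(-300, 600, 1200), c(2, 2, 9), c("a", "b", "c"))
  expect_equal(baselineMedian(m2)$nBaselineWindows, 2)
  expect_equal(baselineMedian(mkMpr(1:4 * 100, c(1, 3, 2, 100),
                                    rep("a", 4)))$baselineMedianMpr, 2.5)
  expect_error(baselineMedian(mkMpr(1000, 1, "a")), "unanalyzable")
})

test_that("baseline-normalized MPR has baseline median exactly 1", {
  set.seed(4)
  times <- seq(-500, 2000, by = 1)
  m <- mkMpr(times, rlnorm(length(times)), rep("s", length(times)))
  nm <- normalizeMpr(m)
  expect_equal(median(normalizedMpr(nm)[times <= 900]), 1, tolerance = 1e-12)
})

test_that("signed-rank test: exact small-sample values and conventions", {
  # 6 values all above the null, no ties: exact two-sided p = 2/2^6
  r <- testSegment(c(1.2, 1.4, 1.1, 1.6, 1.3, 1.5))
  expect_equal(r$pValue, 0.03125)
  expect_equal(r$direction, "above")
  # symmetric pairs about the null: p = 1, no direction
  r2 <- testSegment(c(1 - 0.2, 1 + 0.2, 1 - 0.1, 1 + 0.1))
  expect_equal(r2$pValue, 1)
  expect_equal(r2$direction, "none")
  # all differences zero
  r3 <- testSegment(rep(1, 5))
  expect_equal(r3$pValue, 1)
  expect_equal(r3$direction, "none")
  expect_error(testSegment(numeric(0)), "empty")
})

test_that("signed-rank p matches exhaustive enumeration for n <= 10", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    vals <- 1 + rnorm(n, mean = runif(1, -0.3, 0.3))
    expect_equal(testSegment(vals)$pValue, wilcoxEnumOracle(vals - 1),
                 tolerance = 1e-12)
  }
})

test_that("BH flags match a brute-force step-up oracle", {
  expect_equal(bhAdjust(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bhAdjust(c(1e-5, 0.5), fdr = 1e-4), c(TRUE, FALSE))
  expect_identical(bhAdjust(numeric(0)), logical(0))
  expect_error(bhAdjust(c(0.5, 2)), "\\[0, 1\\]")
  set.seed(7)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(c(1, 3, 6), 1)      # mix of null-ish and small p
    fdr <- sample(c(1e-4, 0.01, 0.05, 0.2), 1)
    expect_identical(bhAdjust(p, fdr), bhStepUpOracle(p, fdr))
  }
})

test_that("Bonferroni rejections are a subset of BH rejections", {
  set.seed(9)
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    p <- runif(m)^3
    alpha <- 0.05
    bonf <- p <= alpha / m
    expect_true(all(bhAdjust(p, fdr = alpha)[bonf]))
  }
})

test_that("onset is the earliest BH-rejected segment above baseline", {
  df <- data.frame(segmentId = c("a", "b", "c", "d"),
                   midpointTime = c(5, 18, 21, 30) * 60,
                   bhReject = c(FALSE, FALSE, TRUE, TRUE),
                   direction = "above")
  expect_equal(onsetTime(detectOnset(df)), 21)
  expect_equal(detectOnset(df)@onsetSegmentId, "c")
  df$bhReject <- FALSE
  expect_true(is.na(onsetTime(detectOnset(df))))
  # a significant below-baseline segment is not an onset
  df2 <- data.frame(segmentId = "x", midpointTime = 1500, bhReject = TRUE,
                    direction = "below")
  expect_true(is.na(onsetTime(detectOnset(df2))))
  # significance inside the baseline window does not count
  df3 <- data.frame(segmentId = "y", midpointTime = 600, bhReject = TRUE,
                    direction = "above")
  expect_true(is.na(onsetTime(detectOnset(df3))))
})

test_that("drift fit recovers exact lines with a degenerate CI", {
  t <- seq(20, 120, by = 5)
  f <- fitDrift(t, 14 - 0.02 * t)
  expect_equal(driftSlope(f), -0.02, tolerance = 1e-10)
  expect_equal(f@slopeCi[1], f@slopeCi[2], tolerance = 1e-8)
  expect_equal(f@intercept, 14, tolerance = 1e-8)
  expect_error(fitDrift(c(5, 10, 20, 25), c(1, 2, 3, 4)), "fewer than 3")
})

test_that("drift fit only uses points after the 15-min cutoff", {
  t <- c(5, 10, seq(20, 100, by = 10))
  y <- 14 - 0.02 * t
  y[1:2] <- 99                      # wild pre-cutoff points must not matter
  expect_equal(driftSlope(fitDrift(t, y)), -0.02, tolerance = 1e-10)
})

test_that("drift fit resists band-edge saturation and gross outliers", {
  set.seed(17)
  t <- seq(20, 180, by = 5)
  y <- 13 - 0.0241 * t + rnorm(length(t), sd = 0.05)
  clean <- fitDrift(t, y, band = c(8, 16), edgeTol = 0.25)
  yOut <- y
  yOut[10] <- 8.1                   # peak stuck at the band's lower edge
  robust <- fitDrift(t, yOut, band = c(8, 16), edgeTol = 0.25)
  expect_equal(driftSlope(robust), driftSlope(clean),
               tolerance = 0.1 * abs(driftSlope(clean)))
  expect_true(10 %in% robust@excluded)
})

test_that("drift slope CI has near-nominal coverage and no slope bias", {
  set.seed(23)
  hits <- 0
  slopes <- numeric(200)
  t <- seq(20, 180, length.out = 50)
  for (i in 1:200) {
    y <- 14 - 0.0241 * t + rnorm(50, sd = 0.1)
    f <- fitDrift(t, y)
    slopes[i] <- driftSlope(f)
    if (f@slopeCi[1] <= -0.0241 && -0.0241 <= f@slopeCi[2]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
  se <- sd(slopes) / sqrt(200)
  expect_lt(abs(mean(slopes) + 0.0241), 2 * se)   # unbiased estimator
})

test_that("bootstrap median CI brackets the median and covers nominally", {
  expect_equal(ciSegmentMedian(rep(3, 10)), c(3, 3))
  expect_equal(ciSegmentMedian(5), c(5, 5))
  set.seed(13)
  x <- rlnorm(40)
  ci <- ciSegmentMedian(x, seed = 2)
  expect_lte(ci[1], median(x))
  expect_gte(ci[2], median(x))
  # reproducible under the same seed
  expect_identical(ci, ciSegmentMedian(x, seed = 2))

  hits <- 0
  for (i in 1:500) {
    y <- rnorm(100)
    ci <- ciSegmentMedian(y, nBoot = 500, seed = 1000 + i)
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
})

test_that("segmentStats assembles per-segment rows with FDR control", {
  set.seed(19)
  times <- c(seq(-100, 19, by = 1), seq(1000, 1119, by = 1))
  vals <- c(rlnorm(120, sd = 0.2), rlnorm(120, sd = 0.2) * 3)
  m <- normalizeMpr(mkMpr(times, vals, rep(c("base", "trem"), each = 120)))
  st <- segmentStats(m)
  expect_equal(nrow(st), 2)
  expect_equal(st$segmentId, c("base", "trem"))
  expect_false(st$bhReject[1])
  expect_true(st$bhReject[2])
  expect_equal(st$direction[2], "above")
  expect_true(all(st$ciLow <= st$medianNormalizedMpr &
                    st$medianNormalizedMpr <= st$ciHigh))
  expect_equal(st$midpointTime, c(-40.5, 1059.5))
  expect_error(segmentStats(mkMpr(1, 1, "a")), "not baseline-normalized")
})
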