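test_that("summed spectrogram adds the three axes and windows correctly", {
  set.seed(3)
  x <- rnorm(500 * 60)
  same3 <- TriaxSegment(cbind(x, x, x), samplingRate = 500, segmentId = "s")
  one <- TriaxSegment(cbind(x, 0 * x, 0 * x), samplingRate = 500,
                      segmentId = "s")
  sp3 <- summedSpectrogram(same3)
  sp1 <- summedSpectrogram(one)
  expect_equal(spectralPower(sp3), 3 * spectralPower(sp1), tolerance = 1e-12)
  expect_equal(nrow(spectralPower(sp3)), 60)       # 60 s -> 60 windows
  expect_equal(diff(freqBins(sp1))[1], 1)          # 1 Hz bin spacing
  expect_error(summedSpectrogram(
    TriaxSegment(matrix(0, 100, 3), samplingRate = 500)), "shorter than 1 s")
})

test_that("a pure tone concentrates within one bin of its frequency", {
  sp <- summedSpectrogram(toneSegment(10, fs = 500, durSec = 20))
  pow <- spectralPower(sp)
  fb <- freqBins(sp)
  near <- abs(fb - 10) <= 1
  frac <- rowSums(pow[, near]) / rowSums(pow)
  expect_true(all(frac >= 0.9))
  # the non-integer study rate puts the tone off-bin: Hamming leakage
  # spreads slightly wider, but stays concentrated within two bins
  sp2 <- summedSpectrogram(toneSegment(10, fs = 1017.3, durSec = 10))
  db2 <- diff(freqBins(sp2))[1]
  frac2 <- rowSums(spectralPower(sp2)[, abs(freqBins(sp2) - 10) <= 2 * db2]) /
    rowSums(spectralPower(sp2))
  expect_true(all(frac2 >= 0.9))
})

test_that("MAD artifact rule matches hand computation and handles MAD = 0", {
  m <- rejectArtifacts(powerSpectrogram(c(1, 1, 1, 1, 100)))
  expect_equal(keptWindows(m), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(m@sessionMedianPower, 1)
  expect_equal(m@sessionMadPower, 0)
  # all equal: deviation 0 is not > 0, everything kept
  expect_true(all(keptWindows(rejectArtifacts(powerSpectrogram(rep(7, 10))))))
})

test_that("MAD rule excludes inflated windows with low false-exclusion", {
  set.seed(42)
  powers <- rnorm(2000, mean = 10, sd = 1)
  inflated <- sample(2000, 100)                 # 5% of windows, x10 power
  powers[inflated] <- powers[inflated] * 10
  keep <- keptWindows(rejectArtifacts(powerSpectrogram(powers)))
  expect_true(all(!keep[inflated]))
  expect_lt(mean(!keep[-inflated]), 0.05)
})

test_that("artifact mask is invariant to global rescaling of the session", {
  set.seed(8)
  sp <- summedSpectrogram(toneSegment(11, durSec = 30, noiseSd = 1))
  scaled <- sp
  scaled@power <- sp@power * 137
  expect_identical(keptWindows(rejectArtifacts(sp)),
                   keptWindows(rejectArtifacts(scaled)))
})

test_that("concatenateClean drops masked seconds and tames junctions", {
  fs <- 100
  seg <- TriaxSegment(matrix(rnorm(fs * 10 * 3), ncol = 3),
                      samplingRate = fs, segmentId = "s")
  keepAll <- rep(TRUE, 10)
  out <- concatenateClean(seg, keepAll)
  expect_equal(nrow(out), fs * 10)
  # alternating keep/drop on 10 s -> 5 s output
  out2 <- concatenateClean(seg, rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(out2), fs * 5)
  expect_equal(nrow(concatenateClean(seg, rep(FALSE, 10))), 0)
  expect_error(concatenateClean(seg, rep(TRUE, 7)), "mask length")

  # step discontinuity across a dropped window: junction jump is bounded
  # below the raw step size by the per-window detrending
  step <- TriaxSegment(matrix(rep(c(0, 10), each = fs * 5 * 3), ncol = 3),
                       samplingRate = fs, segmentId = "st")
  keep <- rep(TRUE, 10); keep[6] <- FALSE
  cc <- concatenateClean(step, keep)
  junction <- abs(cc[fs * 5 + 1, 1] - cc[fs * 5, 1])
  expect_lt(junction, 10)
  expect_lt(junction, 1)   # detrended flat windows join near-seamlessly
})

test_that("Welch grid matches samplingRate/nfft at all study rates", {
  for (fs in c(617, 500, 1017.3)) {
    p <- welchPsd(rnorm(round(fs * 10)), fs)
    expect_equal(diff(p@freqs)[1], fs / p@nfft)
    expect_equal(p@nfft, max(256, 2^ceiling(log2(round(4 * fs)))))
  }
  expect_error(welchPsd(rnorm(100), 500), "shorter than one")
})

test_that("Welch PSD integrates to the signal variance (Parseval)", {
  set.seed(12)
  x <- rnorm(500 * 30)
  p <- welchPsd(x, 500)
  expect_equal(sum(p@power) * diff(p@freqs)[1], var(x), tolerance = 0.05)
})

test_that("peakFrequency finds tones and breaks ties toward low frequency", {
  p <- welchPsd(sin(2 * pi * 11 * (0:(500 * 8 - 1)) / 500) +
                  rnorm(500 * 8, sd = 0.1), 500)
  expect_lt(abs(peakFrequency(p, c(10, 14)) - 11), 500 / p@nfft + 1e-9)
  flat <- new("PSDEstimate", freqs = seq(0, 50, by = 0.5),
              power = rep(1, 101), nfft = 256L, segmentId = "f",
              midpointTime = 0, samplingRate = 128)
  expect_equal(peakFrequency(flat, c(10, 14)), 10)   # tie-break: lowest bin
  expect_error(peakFrequency(flat, c(60, 70)), "empty")
})

test_that("motion power ratio: hand arithmetic and scale invariance", {
  freqs <- 0:30
  flat <- rep(1, 31)
  expect_equal(motionPowerRatio(flat, freqs), 1)    # equal-width bands
  p <- numeric(31)
  p[freqs %in% 10:13] <- 2
  p[freqs %in% 17:20] <- 1
  expect_equal(motionPowerRatio(p, freqs), 2)
  expect_identical(motionPowerRatio(p * 7, freqs),
                   motionPowerRatio(p, freqs))
  expect_true(is.na(motionPowerRatio(numeric(31) + c(rep(1, 15), rep(0, 16)),
                                     freqs)))       # zero reference power
})

test_that("half-open band convention excludes the upper edge", {
  freqs <- 0:30
  p <- numeric(31)
  p[freqs == 14] <- 100   # on the tremor-band upper edge: not counted
  p[freqs %in% 17:20] <- 1
  expect_equal(motionPowerRatio(p, freqs), 0)
})

test_that("selectTremorBand designates bands around spectral modes", {
  mkPsd <- function(centers, heights, t = 1200) {
    freqs <- seq(0, 50, by = 0.25)
    pow <- rep(1, length(freqs))
    for (i in seq_along(centers))
      pow <- pow + heights[i] * exp(-(freqs - centers[i])^2 / 0.5)
    new("PSDEstimate", freqs = freqs, power = pow, nfft = 1024L,
        segmentId = sprintf("s%d", t), midpointTime = t, samplingRate = 500)
  }
  # all peaks at 10 Hz -> band [8, 12)
  b <- selectTremorBand(list(mkPsd(10, 20, 1000), mkPsd(10, 25, 1400)))
  expect_equal(b@tremorBand, c(8, 12))
  # bimodal 6 + 14 Hz -> primary around 14, secondary around 6
  b2 <- selectTremorBand(list(mkPsd(c(6, 14), c(12, 20), 1000),
                              mkPsd(c(6, 14), c(10, 22), 1500)),
                         searchRange = c(4, 16))
  expect_equal(b2@tremorBand, c(12, 16))
  expect_length(b2@secondaryBand, 2)
  expect_lt(abs(mean(b2@secondaryBand) - 6), 1)
  # featureless session -> default band with a warning
  flat <- mkPsd(numeric(0), numeric(0), 1200)
  expect_warning(b3 <- selectTremorBand(list(flat)), "noise floor")
  expect_equal(b3@tremorBand, c(10, 14))
  expect_error(selectTremorBand(list(mkPsd(10, 10, t = 100))),
               "no post-baseline")
})
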