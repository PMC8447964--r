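test_that("identical seeds give bit-identical sessions", {
  a <- simulateSession(plan = smallPlan(seed = 5))
  b <- simulateSession(plan = smallPlan(seed = 5))
  c <- simulateSession(plan = smallPlan(seed = 6))
  for (i in seq_along(segments(a)))
    expect_identical(channels(segments(a)[[i]]), channels(segments(b)[[i]]))
  expect_false(identical(channels(segments(a)[[1]]),
                         channels(segments(c)[[1]])))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulateSession(plan = smallPlan(seed = 5)))
  expect_identical(rnorm(3), before)
})

test_that("noise-free tremor matches the programmed instantaneous frequency", {
  quiet <- NoiseProfile(broadbandSd = 0, lowFreqMotionSd = 0,
                        artifactRate = 0)
  trem <- TremorProfile(onsetTime = 960, peakFreqAtOnset = 12,
                        driftSlope = -0.5, amplitude = 1,
                        intermittencyDuty = 1)
  ses <- simulateSession(trem, quiet, smallPlan(seed = 2))
  post <- segments(ses)[[4]]               # starts 1080 s, fully post-onset
  sp <- summedSpectrogram(post)
  for (w in seq_along(windowTimes(sp))) {
    tw <- windowTimes(sp)[w]
    fProg <- 12 - 0.5 / 60 * (tw - 960)
    fDom <- freqBins(sp)[which.max(spectralPower(sp)[w, ])]
    expect_lt(abs(fDom - fProg), diff(freqBins(sp))[1] + 1e-9)
  }
})

test_that("zero drift with a dominant tone keeps the Welch peak fixed", {
  quiet <- NoiseProfile(broadbandSd = 0.01, lowFreqMotionSd = 0,
                        artifactRate = 0)
  trem <- TremorProfile(onsetTime = 0, peakFreqAtOnset = 11.5,
                        driftSlope = 0, amplitude = 5,
                        intermittencyDuty = 1)
  ses <- simulateSession(trem, quiet, smallPlan(seed = 3))
  post <- Filter(function(s) startTime(s) >= 0, segments(ses))
  peaks <- vapply(post, function(s) {
    p <- welchPsd(channels(s), samplingRate(s))
    peakFrequency(p, c(10, 14))
  }, numeric(1))
  expect_lt(max(peaks) - min(peaks), 500 / 2048 + 1e-9)
})

test_that("tremor is inactive before onset", {
  ses <- simulateSession(TremorProfile(onsetTime = 1500, amplitude = 3),
                         NoiseProfile(broadbandSd = 0.01,
                                      lowFreqMotionSd = 0,
                                      artifactRate = 0),
                         smallPlan(seed = 4))
  pre <- segments(ses)[[1]]                # ends well before onset
  expect_lt(max(abs(channels(pre))), 0.1)
})

test_that("amplitude 0 yields a pure-noise session with no tremor trace", {
  ses <- simulateSession(TremorProfile(amplitude = 0),
                         plan = smallPlan(seed = 6))
  rep <- runPipeline(ses)
  expect_true(is.na(onsetTime(rep$onset)))
})

test_that("artifact windows carry elevated summed power by construction", {
  ses <- simulateSession(TremorProfile(amplitude = 0),
                         NoiseProfile(artifactRate = 6),
                         smallPlan(seed = 8))
  truth <- artifactWindows(ses)
  expect_gt(nrow(truth), 0)
  specs <- sessionSpectrograms(preprocessSession(ses))
  s <- unlist(lapply(specs, function(sp) rowSums(spectralPower(sp))))
  ids <- unlist(lapply(specs, function(sp)
    rep(sp@segmentId, length(windowTimes(sp)))))
  wdx <- unlist(lapply(specs, function(sp) seq_along(windowTimes(sp))))
  isArt <- paste(ids, wdx) %in% paste(truth$segmentId, truth$window)
  expect_true(all(s[isArt] > median(s)))
})

test_that("drift cannot drive the frequency negative", {
  expect_error(simulateSession(
    TremorProfile(onsetTime = 0, peakFreqAtOnset = 1, driftSlope = -3,
                  amplitude = 1),
    plan = smallPlan(seed = 1)), "below 0 Hz")
})

test_that("task simulation follows its design and flags degeneracy", {
  df <- simulateTaskSessions(TaskPlan(seed = 11))
  expect_setequal(unique(df$dose), c(0, 2, 4, 6, 8))
  expect_true(all(df$prematureReaches <= df$attemptedReaches))
  expect_equal(df$sessionMinutes[df$dose == 0][1], 15)
  expect_equal(df$sessionMinutes[df$dose == 8][1], 30)
  # determinism
  expect_identical(df, simulateTaskSessions(TaskPlan(seed = 11)))
  # flat design: dose-response on a zero-variance metric is flagged
  expect_error(doseResponse(c(0, 2, 4), rep(100, 3)), "zero variance")
  expect_error(simulateTaskSessions(TaskPlan(doses = c(0, 2))), "3 distinct")
})

test_that("negative engagement slope yields negative correlations", {
  neg <- 0
  for (s in 1:100) {
    df <- simulateTaskSessions(TaskPlan(seed = s))
    sm <- summarizeSessions(df)
    dr <- doseResponse(sm$perDose$dose, sm$perDose$meanReaches,
                       metric = "reaches")
    if (dr@r < 0) neg <- neg + 1
  }
  expect_gte(neg / 100, 0.90)
})
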