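test_that("cycle segmentation respects the transient-discard rule", {
  cyc <- prtsCycleLowRate()
  rec <- fakeRecording(cyc, cyc * 0.5, 18, sampleRate = 20)
  expect_equal(nCycles(segmentCycles(rec, 20)), 17)
  expect_equal(nCycles(segmentCycles(rec, 20, discardFirst = FALSE)), 18)

  bad <- fakeRecording(rep(cyc, 18), rep(cyc, 18), 1, sampleRate = 20)
  bad@platformTilt <- c(bad@platformTilt, numeric(200))   # 370 s
  bad@comAngle <- c(bad@comAngle, numeric(200))
  bad@hipX <- c(bad@hipX, numeric(200)); bad@shoulderX <- c(bad@shoulderX, numeric(200))
  bad@copX <- c(bad@copX, numeric(200))
  expect_error(segmentCycles(bad, 20), "whole number of cycles")
})

test_that("FRF identities: unity response and pure delay", {
  cyc <- prtsCycleLowRate()
  ex <- excitedFrequencies(buildPRTS(ternaryDesign(), 1.78, nCycles = 1,
                                     sampleRate = 20))
  rec <- fakeRecording(cyc, cyc, 4, sampleRate = 20)
  fr <- estimateFRF(segmentCycles(rec, 20), ex)
  expect_equal(fr@gain, rep(1, length(ex)), tolerance = 1e-9)
  expect_equal(fr@phase, rep(0, length(ex)), tolerance = 1e-9)

  ## circular delay of 0.1 s: phase = -360 f dt within half a degree
  shift <- 2                                  # samples at 20 Hz
  delayed <- c(cyc[(length(cyc) - shift + 1):length(cyc)],
               cyc[1:(length(cyc) - shift)])
  recD <- fakeRecording(cyc, delayed, 4, sampleRate = 20)
  frD <- estimateFRF(segmentCycles(recD, 20), ex)
  expect_equal(frD@phase, -360 * ex * 0.1, tolerance = 0.5)
})

test_that("coherence is 1 for deterministic cycles and ~1/N for unrelated sway", {
  cyc <- prtsCycleLowRate()
  ex <- excitedFrequencies(buildPRTS(ternaryDesign(), 1.78, nCycles = 1,
                                     sampleRate = 20))
  rec <- fakeRecording(cyc, 0.3 * cyc, 5, sampleRate = 20)
  expect_equal(estimateCoherence(segmentCycles(rec, 20), ex),
               rep(1, length(ex)), tolerance = 1e-9)

  ## stimulus-independent response: E[coherence] = 1/N for N averaged cycles
  set.seed(11)
  N <- 17
  meanCoh <- replicate(200, {
    resp <- rnorm(N * length(cyc))
    cs <- cycleSet(matrix(rep(cyc, N), N, byrow = TRUE),
                   matrix(resp, N), 20, 20)
    mean(estimateCoherence(cs, ex))
  })
  expect_lt(abs(mean(meanCoh) - 1 / N), 0.2 * (1 / N))

  expect_error(estimateCoherence(cycleSet(matrix(cyc, 1), matrix(cyc, 1),
                                          20, 20), ex),
               "single cycle")
})

test_that("gain is scale-invariant jointly and linear in the response", {
  cyc <- prtsCycleLowRate()
  ex <- c(0.05, 0.15, 0.25)
  noisyResp <- cyc + rnorm(length(cyc), 0, 0.1)
  base <- segmentCycles(fakeRecording(cyc, noisyResp, 4, sampleRate = 20), 20)
  both <- segmentCycles(fakeRecording(3 * cyc, 3 * noisyResp, 4,
                                      sampleRate = 20), 20)
  respOnly <- segmentCycles(fakeRecording(cyc, 3 * noisyResp, 4,
                                          sampleRate = 20), 20)
  g0 <- estimateFRF(base, ex)@gain
  expect_equal(estimateFRF(both, ex)@gain, g0, tolerance = 1e-12)
  expect_equal(estimateFRF(respOnly, ex)@gain, 3 * g0, tolerance = 1e-12)
})

test_that("coherence is symmetric under stimulus/response exchange", {
  cyc <- prtsCycleLowRate()
  ex <- c(0.05, 0.15, 0.35)
  set.seed(4)
  resp <- 0.5 * cyc + rnorm(length(cyc) * 4, 0, 0.2)
  cs <- cycleSet(matrix(rep(cyc, 4), 4, byrow = TRUE),
                 matrix(resp, 4), 20, 20)
  swapped <- cycleSet(matrix(resp, 4), matrix(rep(cyc, 4), 4, byrow = TRUE),
                      20, 20)
  expect_equal(estimateCoherence(cs, ex), estimateCoherence(swapped, ex),
               tolerance = 1e-12)
})

test_that("frequencies without stimulus energy are dropped with a warning", {
  cyc <- prtsCycleLowRate()
  rec <- fakeRecording(cyc, cyc, 3, sampleRate = 20)
  cs <- segmentCycles(rec, 20)
  ## 0.1 Hz is an even harmonic: structurally null for the PRTS
  expect_warning(fr <- estimateFRF(cs, c(0.05, 0.1, 0.15)),
                 "zero stimulus amplitude")
  expect_equal(fr@freqs, c(0.05, 0.15))
})

test_that("cycle means retain the body-lean offset", {
  cyc <- prtsCycleLowRate()
  rec <- fakeRecording(cyc, 0.5 * cyc + 2.5, 4, sampleRate = 20)
  cm <- cycleMean(segmentCycles(rec, 20))
  expect_equal(mean(cm$response), 0.5 * mean(cyc) + 2.5, tolerance = 1e-12)
  expect_equal(cm$stimulus, cyc, tolerance = 1e-12)
})

test_that("band averaging preserves the overall gain level", {
  cyc <- prtsCycleLowRate()
  ex <- excitedFrequencies(buildPRTS(ternaryDesign(), 1.78, nCycles = 1,
                                     sampleRate = 20))
  fr <- estimateFRF(segmentCycles(fakeRecording(cyc, cyc, 3,
                                                sampleRate = 20), 20), ex)
  ba <- bandAverage(fr, nBands = 6)
  expect_true(all(ba$gain >= min(fr@gain) - 1e-12 &
                  ba$gain <= max(fr@gain) + 1e-12))
  expect_lte(nrow(ba), 6)
})
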