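sr <- 100
tt <- (0:(8 * sr - 1)) / sr

test_that("detrending recovers intercept, slope and residual", {
  line <- 3.3 - 0.05 * tt
  d <- detrendTrial(line, sr)
  expect_equal(d$intercept, 3.3, tolerance = 1e-9)
  expect_equal(d$slope, -0.05, tolerance = 1e-9)
  expect_lt(max(abs(d$residual)), 1e-9)

  ## an oscillation even about the sampled window centre leaves no slope
  ## (odd-symmetric components genuinely project onto the trend)
  cosine <- cos(2 * pi * (tt - mean(tt)))
  expect_lt(abs(detrendTrial(cosine, sr)$slope), 1e-9)

  both <- detrendTrial(1.2 + 0.3 * tt + 0.7 * cos(2 * pi * 1.25 * (tt - mean(tt))), sr)
  expect_equal(both$slope, 0.3, tolerance = 1e-9)
  expect_equal(both$intercept, 1.2, tolerance = 1e-9)

  expect_error(detrendTrial(numeric(100), sr), "8 s")
})

test_that("amplitude spectrum uses time-domain sine scaling", {
  sp <- amplitudeSpectrum(0.5 * sin(2 * pi * tt), sr)
  expect_equal(unname(sp[8]), 0.5, tolerance = 1e-12)   # 1 Hz -> bin 8
  expect_lt(max(sp[-8]), 1e-12)
  expect_lt(max(amplitudeSpectrum(rep(1.7, length(tt)), sr)), 1e-12)
  two <- amplitudeSpectrum(0.4 * sin(2 * pi * tt) +
                           0.9 * sin(2 * pi * 1.25 * tt), sr)
  expect_equal(unname(two[c(8, 10)]), c(0.4, 0.9), tolerance = 1e-12)
})

test_that("PSD partition is exact and counts bins correctly", {
  spStim <- numeric(16); spStim[8] <- 0.7
  p <- partitionPSD(spStim)
  expect_equal(p$stim, p$full); expect_equal(p$low + p$high, 0)

  spLow <- numeric(16); spLow[2] <- 0.4     # 0.25 Hz
  expect_equal(partitionPSD(spLow)$low, partitionPSD(spLow)$full)

  flat <- partitionPSD(rep(0.3, 16))
  expect_equal(c(flat$stim, flat$low, flat$high) / 0.3^2, c(2, 2, 12))
  expect_equal(flat$full, flat$stim + flat$low + flat$high)
})

test_that("feedback score matches the published formula and dominance rule", {
  sp <- numeric(16); sp[8] <- 0.5
  fb1 <- feedbackScore(sp, 0)
  expect_equal(fb1$fb, 50)
  expect_identical(fb1$dominance, "sway")

  fb2 <- feedbackScore(numeric(16), 0.2)
  expect_equal(fb2$fb, 200)
  expect_identical(fb2$dominance, "drift")

  ## amplitudes summing 3 deg with 0.1 deg/s drift: 300/400 = 75% > 70%
  sp3 <- rep(3 / 16, 16)
  fb3 <- feedbackScore(sp3, 0.1)
  expect_equal(fb3$fb, 400)
  expect_identical(fb3$dominance, "sway")

  ## exactly 70% is not dominance (strict inequality)
  spB <- numeric(16); spB[1] <- 0.7
  fbB <- feedbackScore(spB, 0.03)           # 70 sway / 30 drift
  expect_true(is.na(fbB$dominance))
})

test_that("stimulus gain and phase recover amplitude ratios and delays", {
  stim <- buildLearningSequence()
  x <- tiltAngle(stim)
  gp <- stimGainPhase(x, x, sr)
  expect_equal(gp$gain, 1, tolerance = 1e-12)
  expect_equal(gp$phase, 0, tolerance = 1e-9)

  ## half-amplitude response delayed 100 ms: weighted -360 f 0.1
  shift <- round(0.1 * sr)
  xd <- 0.5 * c(x[(length(x) - shift + 1):length(x)], x[1:(length(x) - shift)])
  gpD <- stimGainPhase(xd, x, sr)
  amps <- amplitudeSpectrum(x - mean(x), sr)[c(8, 10)]
  w <- amps / sum(amps)
  expect_equal(gpD$gain, 0.5, tolerance = 1e-9)
  expect_equal(gpD$phase, sum(w * (-360 * c(1, 1.25) * 0.1)), tolerance = 0.5)

  expect_error(stimGainPhase(x, numeric(length(x)), sr), "no energy")
})

test_that("the metrics pipeline is linear-scale covariant", {
  p <- quietParams()
  stim <- buildLearningSequence()
  rec <- simulateSway(stim, balanceModelParams(noiseSd = 4, copNoiseSd = 0),
                      seed = 8, trialLabel = "learning007")
  m1 <- learningTrialMetrics(rec, stim)
  scaled <- new("SwayRecording", platformTilt = platformTilt(rec),
                comAngle = 2 * comAngle(rec), hipX = hipX(rec),
                shoulderX = shoulderX(rec), copX = copX(rec),
                sampleRate = sr, subjectId = "S01",
                trialLabel = "learning007")
  m2 <- learningTrialMetrics(scaled, stim)
  expect_equal(m2$full_psd, 4 * m1$full_psd, tolerance = 1e-9)
  expect_equal(m2$stim_psd, 4 * m1$stim_psd, tolerance = 1e-9)
  expect_equal(m2$drift_slope, 2 * m1$drift_slope, tolerance = 1e-9)
  expect_equal(m2$gain_stim, 2 * m1$gain_stim, tolerance = 1e-9)
  expect_equal(m2$phase_stim, m1$phase_stim, tolerance = 1e-6)
  expect_equal(m2$trial, 7L)
})

test_that("simulated learning trials reproduce the analytic gain and phase", {
  stim <- buildLearningSequence()
  p <- quietParams()
  rec <- simulateSway(stim, p)
  m <- learningTrialMetrics(rec, stim)
  H <- analyticFRF(p, c(1, 1.25))
  amps <- amplitudeSpectrum(tiltAngle(stim) - mean(tiltAngle(stim)), sr)[c(8, 10)]
  w <- amps / sum(amps)
  expect_equal(m$gain_stim, sum(w * Mod(H)), tolerance = 0.02)
  expect_lt(abs(m$phase_stim - sum(w * (Arg(H) * 180 / pi))), 2)
})

test_that("cohort metrics recover the configured stimulus-sway decay", {
  cfg <- learningCohortConfig(nSubjects = 3, nTrials = 12, leanTau = 4,
                              wTau = 4, seed = 21)
  recs <- simulateLearningCohort(cfg)
  met <- learningMetricsTable(recs, buildLearningSequence())
  expect_equal(nrow(met), 36)
  expect_equal(met$full_psd, met$stim_psd + met$low_psd + met$high_psd,
               tolerance = 1e-12)
  ## stimulus-frequency power decays with the drifting sensory weight
  slope <- coef(lm(stim_psd ~ trial, met))[2]
  expect_lt(slope, 0)
  ## and the feedback score reflects the configured mixture scale
  expect_true(all(met$fb > 0))
})
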