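test_that("noise-free calibration recovers the segment geometry exactly", {
  p <- quietParams()
  cal <- fitCalibration(simulateCalibrationTrial(p), p$comHeight)
  truth <- calibrationTruth(p)
  expect_equal(cal@coefHip, unname(truth["coefHip"]), tolerance = 1e-6)
  expect_equal(cal@coefShoulder, unname(truth["coefShoulder"]),
               tolerance = 1e-6)
  expect_equal(cal@intercept, 0, tolerance = 1e-9)
  expect_equal(cal@rSquared, 1, tolerance = 1e-12)
})

test_that("collinear markers are rejected with guidance", {
  p <- quietParams()
  rec <- simulateCalibrationTrial(p, hipSwingAmp = 0)   # no hip motion
  expect_error(fitCalibration(rec, p$comHeight), "hip motion")
})

test_that("coefficients survive 20 dB COP sensor noise (Monte-Carlo)", {
  p0 <- quietParams()
  clean <- simulateCalibrationTrial(p0)
  snrSd <- stats::sd(copX(clean)) / 10               # 20 dB
  truth <- calibrationTruth(p0)
  p <- quietParams(copNoiseSd = snrSd)
  relErr <- t(vapply(1:100, function(s) {
    cal <- fitCalibration(simulateCalibrationTrial(p, seed = s), p$comHeight)
    abs(c(cal@coefHip, cal@coefShoulder) / truth - 1)
  }, numeric(2)))
  expect_lt(max(relErr), 0.05)
})

test_that("applied calibration inverts the geometry", {
  p <- quietParams()
  cal <- fitCalibration(simulateCalibrationTrial(p), p$comHeight)

  ## zero translations map to zero degrees
  zero <- fakeRecording(numeric(100), numeric(100), 1, sampleRate = 10)
  expect_equal(applyCalibration(cal, zero), rep(0, 100), tolerance = 1e-9)

  ## a pure COM translation of h sin(2 deg) maps back to 2 degrees
  m <- new("CalibrationModel", coefHip = 1, coefShoulder = 0, intercept = 0,
           comHeight = p$comHeight, rSquared = 1)
  lift <- p$comHeight * sin(2 * pi / 180)
  rec <- new("SwayRecording", platformTilt = numeric(10),
             comAngle = rep(NA_real_, 10), hipX = rep(lift, 10),
             shoulderX = numeric(10), copX = numeric(10), sampleRate = 10,
             subjectId = "x", trialLabel = "x")
  expect_equal(applyCalibration(m, rec), rep(2, 10), tolerance = 1e-9)

  ## non-physical translations are refused
  recBad <- new("SwayRecording", platformTilt = numeric(10),
                comAngle = rep(NA_real_, 10), hipX = rep(2, 10),
                shoulderX = numeric(10), copX = numeric(10), sampleRate = 10,
                subjectId = "x", trialLabel = "x")
  expect_error(applyCalibration(m, recBad), "non-physical")
})

test_that("calibrated COM tracks the simulator truth channel", {
  p <- quietParams(hipAmp = 0.5)
  cal <- fitCalibration(simulateCalibrationTrial(p), p$comHeight)
  stim <- buildPRTS(ternaryDesign(), 1.78, nCycles = 2)
  rec <- simulateSway(stim, p, seed = 2)
  com <- applyCalibration(cal, rec)
  rmse <- sqrt(mean((com - comAngle(rec))^2))
  expect_lt(rmse, 0.05)
})

test_that("calibration is affine-equivariant under common-mode shifts", {
  p <- quietParams(copNoiseSd = 1e-4)
  rec <- simulateCalibrationTrial(p, seed = 9)
  cal <- fitCalibration(rec, p$comHeight)
  shift <- new("SwayRecording", platformTilt = platformTilt(rec),
               comAngle = comAngle(rec), hipX = hipX(rec) + 0.02,
               shoulderX = shoulderX(rec) + 0.02, copX = copX(rec) + 0.005,
               sampleRate = sampleRate(rec), subjectId = "x",
               trialLabel = "x")
  calS <- fitCalibration(shift, p$comHeight)
  expect_equal(calS@coefHip, cal@coefHip, tolerance = 1e-9)
  expect_equal(calS@coefShoulder, cal@coefShoulder, tolerance = 1e-9)
  ## only the intercept absorbs the offsets
  expect_equal(calS@intercept,
               cal@intercept + 0.005 - 0.02 * (cal@coefHip + cal@coefShoulder),
               tolerance = 1e-9)
})
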