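test_that("analytic closed-loop response has the expected limits", {
  p <- quietParams()
  ## integral control pins the low-frequency gain at the sensory weight
  expect_equal(Mod(analyticFRF(p, 1e-4)), p$wProp, tolerance = 1e-3)
  ## no platform coupling, no response
  p0 <- quietParams(wProp = 0)
  expect_equal(Mod(analyticFRF(p0, c(0.05, 0.5, 2))), rep(0, 3))
  ## resonance peak exceeds the high-frequency response
  g <- Mod(analyticFRF(p, seq(0.02, 3, by = 0.01)))
  expect_gt(max(g), Mod(analyticFRF(p, 3)))
  ## and sits in the band reported for tilt posturography
  fpk <- seq(0.02, 3, by = 0.01)[which.max(g)]
  expect_gt(fpk, 0.1); expect_lt(fpk, 0.3)
})

test_that("unstable parameter sets are rejected with a diagnostic", {
  expect_error(balanceModelParams(Kd = 1, noiseSd = 0), "unstable")
  p <- balanceModelParams(Kd = 1, noiseSd = 0, check = FALSE)
  expect_error(analyticFRF(p, 0.5), "unstable")
})

test_that("quiet stance with zero setpoint produces zero sway", {
  d <- ternaryDesign()
  stim <- buildPRTS(d, 0, nCycles = 1)      # constant-zero stimulus
  p <- quietParams(leanSetpoint = 0)
  rec <- simulateSway(stim, p)
  expect_lt(max(abs(comAngle(rec))), 1e-10)
  expect_lt(max(abs(copX(rec))), 1e-10)
})

test_that("simulation is deterministic given the seed", {
  stim <- buildLearningSequence()
  p <- balanceModelParams()
  r1 <- simulateSway(stim, p, seed = 42)
  r2 <- simulateSway(stim, p, seed = 42)
  expect_identical(comAngle(r1), comAngle(r2))
  expect_identical(copX(r1), copX(r2))
  r3 <- simulateSway(stim, p, seed = 43)
  expect_false(identical(comAngle(r1), comAngle(r3)))
})

test_that("noise-free simulation matches the analytic FRF and unit coherence", {
  d <- ternaryDesign()
  stim <- buildPRTS(d, 1.78, nCycles = 6)
  p <- quietParams()
  rec <- simulateSway(stim, p)
  cs <- segmentCycles(rec, 20)[-1, ]        # two settling cycles in total
  fr <- estimateFRF(cs, excitedFrequencies(stim), withCoherence = TRUE)
  H <- analyticFRF(p, fr@freqs)
  expect_lt(max(abs(fr@gain / Mod(H) - 1)), 0.02)
  perr <- abs((fr@phase - Arg(H) * 180 / pi + 180) %% 360 - 180)
  expect_lt(max(perr), 2)
  expect_true(all(abs(fr@coherence - 1) < 0.01))
  ## simulated gain never exceeds the analytic peak by more than 5%
  peak <- max(Mod(analyticFRF(p, seq(0.02, 3, by = 0.005))))
  expect_lt(max(fr@gain), 1.05 * peak)
})

test_that("the linear regime obeys superposition", {
  d <- ternaryDesign()
  a <- buildPRTS(d, 0.44, nCycles = 2)
  b <- buildLearningSequence()
  nb <- length(tiltAngle(b))
  ## embed the 8-s learning trace in the 40-s window
  bs <- new("StimulusSequence",
            samples = rep(tiltAngle(b), length.out = length(tiltAngle(a))),
            velocity = rep(tiltVelocity(b), length.out = length(tiltAngle(a))),
            sampleRate = 100, cycleDuration = 8, nCycles = 5L,
            excitedFrequencies = c(1, 1.25), label = "learning",
            velocityMagnitude = NA_real_, config = list())
  ab <- new("StimulusSequence",
            samples = tiltAngle(a) + tiltAngle(bs),
            velocity = tiltVelocity(a) + tiltVelocity(bs),
            sampleRate = 100, cycleDuration = 40, nCycles = 1L,
            excitedFrequencies = numeric(0), label = "custom",
            velocityMagnitude = NA_real_, config = list())
  p <- quietParams(leanSetpoint = 0)
  ra <- comAngle(simulateSway(a, p))
  rb <- comAngle(simulateSway(bs, p))
  rab <- comAngle(simulateSway(ab, p))
  expect_equal(rab, ra + rb, tolerance = 1e-9)
})

test_that("coherence decreases monotonically with torque noise", {
  d <- ternaryDesign()
  stim <- buildPRTS(d, 1.78, nCycles = 5)
  coh <- vapply(c(0, 8, 25), function(ns) {
    p <- balanceModelParams(noiseSd = ns, copNoiseSd = 0)
    cs <- segmentCycles(simulateSway(stim, p, seed = 5), 20)
    mean(estimateCoherence(cs, excitedFrequencies(stim)))
  }, numeric(1))
  expect_true(all(diff(coh) < 0))
  expect_equal(coh[1], 1, tolerance = 0.01)
})

test_that("excessive tilt drives a simulated fall", {
  stim <- buildPRTS(ternaryDesign(), 60, nCycles = 1)
  expect_error(simulateSway(stim, quietParams()), "simulated fall")
})

test_that("optional sensory reweighting lowers gain for larger amplitudes", {
  d <- ternaryDesign()
  gainAt <- function(p) {
    g <- numeric(2)
    for (i in 1:2) {
      stim <- buildPRTS(d, c(0.44, 1.78)[i], nCycles = 4)
      cs <- segmentCycles(simulateSway(stim, p), 20)
      fr <- estimateFRF(cs, excitedFrequencies(stim))
      g[i] <- fr@gain[fr@freqs == 0.15]
    }
    g
  }
  gLin <- gainAt(quietParams())
  expect_equal(gLin[1], gLin[2], tolerance = 1e-6)   # linear model: no effect
  gNl <- gainAt(quietParams(reweightExponent = 0.3))
  expect_gt(gNl[1], gNl[2])                          # enabled: pp4 < pp1
})

test_that("learning cohorts have the configured size and drift truth", {
  cfg <- learningCohortConfig(nSubjects = 1, nTrials = 2,
                              params = quietParams(check = FALSE), seed = 3)
  recs <- simulateLearningCohort(cfg)
  expect_length(recs, 2)
  tr <- attr(recs, "truth")
  expect_equal(tr$trial, 0:1)

  cfgNull <- learningCohortConfig(nSubjects = 2, nTrials = 3, drift = FALSE,
                                  seed = 3)
  trNull <- attr(simulateLearningCohort(cfgNull), "truth")
  for (s in unique(trNull$subject)) {
    sub <- trNull[trNull$subject == s, ]
    expect_equal(diff(sub$lean_deg), rep(0, 2))
    expect_equal(diff(sub$w_prop), rep(0, 2))
  }

  cfgDrift <- learningCohortConfig(nSubjects = 1, nTrials = 75,
                                   subjectSd = list(lean = 0, logKp = 0, w = 0),
                                   seed = 3)
  trD <- attr(simulateLearningCohort(cfgDrift), "truth")
  expect_equal(trD$lean_deg[1], 3.3, tolerance = 0.05)
  expect_equal(trD$lean_deg[75], 2.4, tolerance = 0.05)
  expect_true(all(diff(trD$lean_deg) < 0))
})
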