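test_that("maximal-length ternary sequence has full period and balanced symbols", {
  s <- generateTernarySymbols(ternaryDesign())
  expect_length(s, 80)                       # 3^4 - 1
  counts <- table(factor(s, levels = c(-1, 0, 1)))
  expect_equal(unname(counts[["1"]]), 27)
  expect_equal(unname(counts[["-1"]]), 27)
  expect_equal(unname(counts[["0"]]), 26)
  expect_equal(sum(s), 0)                    # zero net displacement per cycle
})

test_that("non-primitive and degenerate tap sets are rejected with diagnostics", {
  bad <- ternaryDesign(taps = c(0L, 0L, 1L, 2L))   # period 26, not 80
  expect_error(generateTernarySymbols(bad), "period 26")
  expect_error(ternaryDesign(taps = c(1L, 0L, 0L, 0L)), "degenerate")
})

test_that("printed step velocities integrate to the printed amplitudes", {
  d <- ternaryDesign()
  pp <- vapply(c(0.44, 0.89, 1.78), function(v)
    diff(range(tiltAngle(buildPRTS(d, v, nCycles = 1)))), numeric(1))
  expect_equal(pp, c(1, 2, 4), tolerance = 0.011)
  ## one shared design: peak-to-peak per unit velocity is a single constant
  expect_equal(pp / c(0.44, 0.89, 1.78), rep(pp[3] / 1.78, 3),
               tolerance = 1e-12)
})

test_that("PRTS traces are periodic, continuous and linear in velocity", {
  d <- ternaryDesign()
  s2 <- buildPRTS(d, 0.89, nCycles = 3)
  x <- tiltAngle(s2)
  n <- length(x) / 3
  ## each cycle starts at the angle the previous one returned to
  expect_equal(x[n + 1], x[1])
  expect_equal(x[2 * n + 1], x[1])
  ## continuity: per-sample increments bounded by velocity * dt
  expect_lte(max(abs(diff(x))), 0.89 / 100 + 1e-12)
  ## doubling velocity exactly doubles the excursion
  expect_equal(2 * tiltAngle(buildPRTS(d, 0.5, nCycles = 1)),
               tiltAngle(buildPRTS(d, 1.0, nCycles = 1)))
  ## degenerate zero velocity
  expect_true(all(tiltAngle(buildPRTS(d, 0, nCycles = 1)) == 0))
})

test_that("velocity staircase spectrum is flat across odd harmonics (DFT oracle)", {
  d <- ternaryDesign()
  stim <- buildPRTS(d, 1.78, nCycles = 1)
  ## independent DFT of the velocity staircase
  vel <- rep(generateTernarySymbols(d) * 1.78, each = 25)
  amp <- 2 * Mod(fft(vel))[-1] / length(vel)
  kmax <- 44                                  # analysis band 2.2 Hz
  odd <- seq(1, kmax, by = 2); even <- seq(2, kmax, by = 2)
  expect_lt(max(amp[even]), 1e-10 * max(amp[odd]))   # structural nulls
  ## ripple across the band stays well above the 10% excitation threshold
  expect_gt(min(amp[odd]) / max(amp[odd]), 0.5)
  expect_equal(excitedFrequencies(stim), odd / 20)
})

test_that("step boundaries must fall on samples", {
  expect_error(buildPRTS(ternaryDesign(), 1, sampleRate = 30),
               "step boundaries")
})

test_that("learning sequence reproduces the printed extremes with toes-down bias", {
  pars <- learningStimulusParams()
  stim <- buildLearningSequence(pars)
  ## continuous extremes are matched exactly by the solver
  tt <- seq(0, 8, by = 1e-5)
  trace <- pars$offset + pars$a1 * sin(2 * pi * tt) +
    pars$a2 * sin(2.5 * pi * tt)
  expect_equal(min(trace), -5.3, tolerance = 1e-6)
  expect_equal(max(trace), 2.6, tolerance = 1e-6)
  ## toes-down magnitude exceeds toes-up magnitude
  expect_gt(-min(tiltAngle(stim)), max(tiltAngle(stim)))
  ## integer cycle counts: 8 x 1 Hz and 10 x 1.25 Hz -> periodic
  expect_equal(tiltAngle(stim)[1], trace[length(trace)], tolerance = 1e-9)
  ## the platform starts at rest
  expect_equal(pars$a1 * pars$f1 + pars$a2 * pars$f2, 0, tolerance = 1e-12)
})

test_that("degenerate and invalid learning parameters are handled", {
  pars <- learningStimulusParams()
  pars$a1 <- 0; pars$a2 <- 0; pars$offset <- 1.2
  expect_true(all(tiltAngle(buildLearningSequence(pars)) == 1.2))
  pars$f2 <- 1.3                       # 10.4 cycles in 8 s
  expect_error(buildLearningSequence(pars), "whole numbers")
})

test_that("session assembly yields the 120-s warm-up and 360-s test sequences", {
  ses <- assembleSession(seed = 7)
  dur <- function(s) length(tiltAngle(s)) / sampleRate(s)
  expect_equal(dur(ses$warmup), 120)
  expect_equal(unname(vapply(ses$test, dur, numeric(1))), rep(360, 3))
  expect_setequal(ses$order, c("pp1", "pp2", "pp4"))
  ## seeded order is reproducible
  expect_identical(ses$order, assembleSession(seed = 7)$order)
})
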