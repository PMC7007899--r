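## Stimulus construction: pseudo-random ternary tilt sequences (PRTS) and the
## rhythmic two-sine learning sequence.

#' Default pseudo-random ternary design
#'
#' Constructs the ternary shift-register design used for the platform tilt
#' staircase.  The default is the degree-4 recurrence
#' `s_n = s_(n-1) + s_(n-4) (mod 3)` with symbols `(0, 1, 2)` mapped to
#' velocity signs `(0, +1, -1)`, a maximal-length configuration (period 80)
#' whose cumulative-sum excursion is exactly 9 steps.  With 0.25-s steps the
#' 20-s cycle then integrates the printed step velocities 0.44, 0.89 and
#' 1.78 deg/s into peak-to-peak tilt amplitudes of 1, 2 and 4 degrees.
#'
#' @param registerOrder degree of the recurrence (period `3^m - 1`).
#' @param taps recurrence coefficients, most recent symbol first.
#' @param symbolMap mapping of field symbols `(0, 1, 2)` to `{-1, 0, +1}`.
#' @param stepDuration velocity step duration, seconds.
#' @return a [TernaryDesign-class].
#' @examples
#' d <- ternaryDesign()
#' cycleDuration(d)            # 20 s
#' @export
ternaryDesign <- function(registerOrder = 4L, taps = c(1L, 0L, 0L, 1L),
                          symbolMap = c(0L, 1L, -1L), stepDuration = 0.25) {
  new("TernaryDesign", registerOrder = as.integer(registerOrder),
      taps = as.integer(taps), symbolMap = as.integer(symbolMap),
      stepDuration = stepDuration)
}

#' Generate one period of a maximal-length ternary sequence
#'
#' Runs the shift-register recurrence from the seed state `(0, ..., 0, 1)`
#' and maps field symbols to velocity signs.  The recurrence must be
#' primitive: the register state must first return to the seed after exactly
#' `3^m - 1` steps.  Non-primitive tap sets are rejected with the achieved
#' period in the error message.
#'
#' @param design a [TernaryDesign-class].
#' @return integer vector of length `3^m - 1` over `{-1, 0, +1}`.
#' @examples
#' s <- generateTernarySymbols(ternaryDesign())
#' length(s)                   # 80
#' table(s)                    # 26 zeros, 27 each of -1 / +1
#' @export
generateTernarySymbols <- function(design) {
  stopifnot(is(design, "TernaryDesign"))
  m <- design@registerOrder
  nmax <- 3^m - 1
  ## state holds (s_{n-m}, ..., s_{n-1}); taps are ordered most recent first
  tapsRev <- rev(design@taps)
  state0 <- c(rep(0L, m - 1L), 1L)
  state <- state0
  symbols <- integer(nmax)
  period <- NA_integer_
  for (i in seq_len(nmax + 1L)) {
    nxt <- sum(tapsRev * state) %% 3L
    if (i <= nmax) symbols[i] <- nxt
    state <- c(state[-1L], nxt)
    if (all(state == 0L))
      stop("degenerate register: taps drive the state to all-zero", call. = FALSE)
    if (all(state == state0)) { period <- i; break }
  }
  if (is.na(period) || period != nmax)
    stop(sprintf("taps are not primitive: achieved period %s instead of %d",
                 ifelse(is.na(period), paste0(">", nmax + 1L), period), nmax),
         call. = FALSE)
  design@symbolMap[symbols + 1L]
}

## internal: velocity staircase (deg/s) for one cycle at a given sample rate
prtsStaircase <- function(design, velocityMagnitude, sampleRate) {
  spb <- design@stepDuration * sampleRate
  if (abs(spb - round(spb)) > 1e-9)
    stop(sprintf(paste0("sampleRate %g is incompatible with stepDuration %g: ",
                        "step boundaries must fall on samples"),
                 sampleRate, design@stepDuration), call. = FALSE)
  symbols <- generateTernarySymbols(design)
  rep(symbols * velocityMagnitude, each = round(spb))
}

#' Build a pseudo-random ternary tilt stimulus
#'
#' Scales the ternary symbol staircase to `+-velocityMagnitude` deg/s,
#' integrates it to a continuous piecewise-linear tilt-angle trace starting
#' at 0 degrees, and repeats it for `nCycles` cycles.  Excited frequencies
#' are the cycle harmonics at which the velocity-staircase amplitude
#' spectrum reaches `excitedThreshold` of its maximum (the even harmonics of
#' a ternary maximal-length sequence are structurally null), capped at
#' `maxFreq`.
#'
#' @param design a [TernaryDesign-class].
#' @param velocityMagnitude nonzero step velocity, deg/s (>= 0).
#' @param nCycles number of consecutive cycles.
#' @param sampleRate sampling rate, Hz; must place step boundaries on samples.
#' @param excitedThreshold relative amplitude threshold for excited harmonics.
#' @param maxFreq upper edge of the analysis band, Hz.
#' @return a [StimulusSequence-class]; peak-to-peak amplitude is
#'   `9 * stepDuration * velocityMagnitude` for the default design.
#' @examples
#' pp4 <- buildPRTS(ternaryDesign(), velocityMagnitude = 1.78, nCycles = 1)
#' diff(range(tiltAngle(pp4)))       # ~4 degrees peak-to-peak
#' @export
buildPRTS <- function(design, velocityMagnitude, nCycles = 18L,
                      sampleRate = 100, excitedThreshold = 0.1,
                      maxFreq = 2.2) {
  stopifnot(is(design, "TernaryDesign"))
  stopIfNot1(velocityMagnitude, "velocityMagnitude")
  if (velocityMagnitude < 0) stop("velocityMagnitude must be >= 0")
  nCycles <- as.integer(nCycles)
  if (nCycles < 1L) stop("nCycles must be >= 1")

  vel1 <- prtsStaircase(design, velocityMagnitude, sampleRate)
  pos1 <- c(0, cumsum(vel1)[-length(vel1)]) / sampleRate
  Tcyc <- cycleDuration(design)

  excited <- numeric(0)
  if (velocityMagnitude > 0) {
    N <- length(vel1)
    amp <- 2 * Mod(stats::fft(vel1))[-1L] / N
    kmax <- min(floor(maxFreq * Tcyc), floor(N / 2))
    k <- seq_len(kmax)
    excited <- k[amp[k] >= excitedThreshold * max(amp[k])] / Tcyc
  }

  pp <- diff(range(pos1))
  label <- if (velocityMagnitude == 0) "custom"
           else if (abs(pp - 1) < 0.05) "pp1"
           else if (abs(pp - 2) < 0.05) "pp2"
           else if (abs(pp - 4) < 0.05) "pp4"
           else "custom"

  new("StimulusSequence",
      samples = rep(pos1, nCycles), velocity = rep(vel1, nCycles),
      sampleRate = sampleRate, cycleDuration = Tcyc, nCycles = nCycles,
      excitedFrequencies = excited, label = label,
      velocityMagnitude = velocityMagnitude,
      config = list(registerOrder = design@registerOrder, taps = design@taps,
                    symbolMap = design@symbolMap,
                    stepDuration = design@stepDuration,
                    excitedThreshold = excitedThreshold, maxFreq = maxFreq))
}

#' Solve the learning-stimulus parameters from its printed extremes
#'
#' The 8-s learning sequence is `offset + a1 sin(2 pi f1 t) +
#' a2 sin(2 pi f2 t)` with f1 = 1 Hz (8 cycles) and f2 = 1.25 Hz
#' (10 cycles).  Its published description fixes only the two extremes
#' (maximum toes-down and toes-up tilt), which under-determines the four
#' free parameters.  This deterministic solver fixes both phases at zero,
#' ties `a2 = -a1 f1 / f2` so the platform starts at rest (zero initial
#' velocity), and solves `a1` and `offset` so the trace extremes equal the
#' requested values exactly (toes-up positive, toes-down negative).
#'
#' @param f1,f2 component frequencies, Hz.
#' @param duration sequence duration, seconds; `duration * f1` and
#'   `duration * f2` must be integers.
#' @param maxToesDown,maxToesUp extreme tilt magnitudes, degrees.
#' @return named list with `f1`, `f2`, `a1`, `a2`, `phase1`, `phase2`,
#'   `offset`, `duration` (degrees / radians / seconds).
#' @export
learningStimulusParams <- function(f1 = 1, f2 = 1.25, duration = 8,
                                   maxToesDown = 5.3, maxToesUp = 2.6) {
  if (abs(duration * f1 - round(duration * f1)) > 1e-9 ||
      abs(duration * f2 - round(duration * f2)) > 1e-9)
    stop("duration must contain whole numbers of both sine cycles")
  ratio <- -f1 / f2
  g <- function(t) sin(2 * pi * f1 * t) + ratio * sin(2 * pi * f2 * t)
  ## locate extremes on a fine grid, refine with local optimisation
  tg <- seq(0, duration, by = 1e-3)
  gg <- g(tg)
  refine <- function(idx, maximise) {
    lo <- tg[max(idx - 2L, 1L)]; hi <- tg[min(idx + 2L, length(tg))]
    stats::optimize(g, c(lo, hi), maximum = maximise)
  }
  gmax <- refine(which.max(gg), TRUE)$objective
  gmin <- refine(which.min(gg), FALSE)$minimum
  gmin <- stats::optimize(g, c(tg[max(which.min(gg) - 2L, 1L)],
                               tg[min(which.min(gg) + 2L, length(tg))]))$objective
  a1 <- (maxToesUp + maxToesDown) / (gmax - gmin)
  offset <- maxToesUp - a1 * gmax
  list(f1 = f1, f2 = f2, a1 = a1, a2 = a1 * ratio, phase1 = 0, phase2 = 0,
       offset = offset, duration = duration)
}

#' Build the rhythmic learning stimulus
#'
#' Samples the two-sine learning sequence
#' `offset + a1 sin(2 pi f1 t + phase1) + a2 sin(2 pi f2 t + phase2)`.
#' With the default solved parameters the trace reaches 5.3 degrees
#' toes-down and 2.6 degrees toes-up (toes-down bias).  The velocity slot
#' carries the analytic derivative sampled at sample midpoints.
#'
#' @param params parameter list from [learningStimulusParams()].
#' @param sampleRate sampling rate, Hz.
#' @return a [StimulusSequence-class] with label `"learning"` and excited
#'   frequencies `c(f1, f2)`.
#' @examples
#' stim <- buildLearningSequence()
#' range(tiltAngle(stim))      # c(-5.3, 2.6)
#' @export
buildLearningSequence <- function(params = learningStimulusParams(),
                                  sampleRate = 100) {
  with(params, {
    if (abs(duration * f1 - round(duration * f1)) > 1e-9 ||
        abs(duration * f2 - round(duration * f2)) > 1e-9)
      stop("duration must contain whole numbers of both sine cycles")
    n <- round(duration * sampleRate)
    tt <- (0:(n - 1)) / sampleRate
    tm <- tt + 0.5 / sampleRate
    trace <- offset + a1 * sin(2 * pi * f1 * tt + phase1) +
      a2 * sin(2 * pi * f2 * tt + phase2)
    vel <- a1 * 2 * pi * f1 * cos(2 * pi * f1 * tm + phase1) +
      a2 * 2 * pi * f2 * cos(2 * pi * f2 * tm + phase2)
    new("StimulusSequence",
        samples = trace, velocity = vel, sampleRate = sampleRate,
        cycleDuration = duration, nCycles = 1L,
        excitedFrequencies = c(f1, f2), label = "learning",
        velocityMagnitude = NA_real_, config = params)
  })
}

#' Assemble the stimulus set of one session
#'
#' Builds the 120-s warm-up sequence (two cycles of each PRTS amplitude,
#' smallest first) and the three full-length test sequences, the latter in
#' a seeded random order of amplitudes.
#'
#' @param design a [TernaryDesign-class].
#' @param velocities named vector of step velocities, deg/s.  The defaults
#'   integrate to the standard 1, 2 and 4 degree peak-to-peak amplitudes.
#' @param nCycles cycles per test sequence.
#' @param sampleRate sampling rate, Hz.
#' @param seed integer seed for the amplitude order.
#' @return list with elements `warmup` (one [StimulusSequence-class]),
#'   `test` (list of three [StimulusSequence-class] in presentation order)
#'   and `order` (the presented amplitude labels).
#' @export
assembleSession <- function(design = ternaryDesign(),
                            velocities = c(pp1 = 0.44, pp2 = 0.89, pp4 = 1.78),
                            nCycles = 18L, sampleRate = 100, seed = 1L) {
  if (length(velocities) != 3L)
    stop("all three PRTS amplitudes are required")
  test <- lapply(velocities, function(v)
    buildPRTS(design, v, nCycles = nCycles, sampleRate = sampleRate))
  names(test) <- names(velocities)

  ## warm-up: two cycles of each amplitude, concatenated
  warm <- lapply(velocities, function(v)
    buildPRTS(design, v, nCycles = 2L, sampleRate = sampleRate))
  warmSamples <- unlist(lapply(warm, tiltAngle), use.names = FALSE)
  warmVel <- unlist(lapply(warm, tiltVelocity), use.names = FALSE)
  warmup <- new("StimulusSequence",
                samples = warmSamples, velocity = warmVel,
                sampleRate = sampleRate, cycleDuration = cycleDuration(design),
                nCycles = 6L,
                excitedFrequencies = excitedFrequencies(test[[1L]]),
                label = "warmup", velocityMagnitude = NA_real_,
                config = list(velocities = velocities))

  seeds <- deriveSeeds(seed, 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seeds[1L])
  ord <- sample(names(velocities))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  list(warmup = warmup, test = test[ord], order = ord)
}
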