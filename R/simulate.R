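## Closed-loop inverted-pendulum sway simulator: delayed PID feedback with
## proprioceptive/graviceptive weighting, low-pass filtered torque noise and
## a two-segment output geometry for markers, COP and the COM truth channel.

#' @useDynLib posturolab, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

GRAVITY <- 9.81
FALL_LIMIT_DEG <- 30

#' Balance model parameters
#'
#' Parameter set of the single-link delayed-feedback balance model
#' `J theta'' = m g h theta + T(t - delay)`, with PID control
#' `T = Kp e + Kd e' + Ki int(e)` acting on the weighted orientation error
#' `e = wProp (u - theta) + (1 - wProp)(0 - theta) + leanSetpoint`, where `u`
#' is the platform tilt: `wProp` references the error to the platform
#' (proprioceptive channel), `1 - wProp` to gravitational vertical.
#' Controller gains default to multiples of the gravitational stiffness
#' `m g h`; the defaults place the closed-loop gain peak near 0.11 Hz
#' (analytic peak gain 1.9), in the band typical of tilt posturography.
#'
#' Closed-loop stability is verified at construction by simulating an
#' impulse response and requiring it to decay.
#'
#' @param bodyMass body mass, kg.
#' @param bodyHeight body height, m (anthropometric fractions scale with it).
#' @param wProp proprioceptive weight in `[0, 1]`.
#' @param Kp,Kd,Ki controller gains (N m/rad, N m s/rad, N m/(rad s));
#'   `NULL` selects the defaults 1.5, 0.5 and 0.06 times `m g h`.
#' @param delay feedback transport delay, s (rounded to whole samples).
#' @param noiseSd stationary sd of the internal torque noise, N m.
#' @param noiseTau time constant of the first-order noise low-pass, s.
#' @param leanSetpoint forward-lean setpoint, degrees.
#' @param copNoiseSd COP sensor noise sd, m.
#' @param markerNoiseSd marker sensor noise sd, m.
#' @param hipAmp,hipFreq amplitude (degrees) and frequency (Hz) of a small
#'   prescribed hip-angle oscillation superposed on the output geometry.
#' @param reweightExponent amplitude nonlinearity: the effective
#'   proprioceptive weight is scaled by
#'   `(peak-to-peak / 1 deg)^(-reweightExponent)` for peak-to-peak > 1 deg.
#'   0 (default) keeps the model linear.
#' @param anthro anthropometric fractions of `bodyHeight` / `bodyMass`; see
#'   the vignette.  `comHeight` and inertia are derived from them.
#' @param check verify closed-loop stability (impulse decay) now.
#' @return a validated parameter list (class `"BalanceModelParams"`).
#' @examples
#' p <- balanceModelParams()
#' p$comHeight
#' @export
balanceModelParams <- function(bodyMass = 66.8, bodyHeight = 1.73,
                               wProp = 0.6, Kp = NULL, Kd = NULL, Ki = NULL,
                               delay = 0.15, noiseSd = 8, noiseTau = 1,
                               leanSetpoint = 2.5, copNoiseSd = 5e-4,
                               markerNoiseSd = 0, hipAmp = 0, hipFreq = 0.05,
                               reweightExponent = 0,
                               anthro = list(legMassFrac = 0.322,
                                             legComFrac = 0.25,
                                             hipHeightFrac = 0.53,
                                             shoulderHeightFrac = 0.82,
                                             hatComAboveHipFrac = 0.18),
                               check = TRUE) {
  if (wProp < 0 || wProp > 1) stop("wProp must lie in [0, 1]")
  if (delay < 0) stop("delay must be >= 0")
  if (noiseSd < 0 || copNoiseSd < 0 || markerNoiseSd < 0)
    stop("noise standard deviations must be >= 0")
  comHeight <- bodyHeight *
    (anthro$legMassFrac * anthro$legComFrac +
     (1 - anthro$legMassFrac) *
       (anthro$hipHeightFrac + anthro$hatComAboveHipFrac))
  mgh <- bodyMass * GRAVITY * comHeight
  inertia <- 0.3 * bodyMass * bodyHeight^2
  if (is.null(Kp)) Kp <- 1.5 * mgh
  if (is.null(Kd)) Kd <- 0.5 * mgh
  if (is.null(Ki)) Ki <- 0.06 * mgh
  p <- structure(list(
    bodyMass = bodyMass, bodyHeight = bodyHeight, comHeight = comHeight,
    inertia = inertia, mgh = mgh, Kp = Kp, Kd = Kd, Ki = Ki, delay = delay,
    wProp = wProp, noiseSd = noiseSd, noiseTau = noiseTau,
    leanSetpoint = leanSetpoint, copNoiseSd = copNoiseSd,
    markerNoiseSd = markerNoiseSd, hipAmp = hipAmp, hipFreq = hipFreq,
    reweightExponent = reweightExponent, anthro = anthro),
    class = "BalanceModelParams")
  if (check) checkStability(p)
  p
}

## internal: raw integrator call on radian traces
runLoop <- function(u, du, p, sampleRate, wEff = p$wProp, noise = NULL,
                    theta0 = NULL) {
  dt <- 1 / sampleRate
  dlay <- round(p$delay * sampleRate)
  if (abs(p$delay * sampleRate - dlay) > 1e-6)
    warning("delay rounded to a whole number of samples")
  r <- deg2rad(p$leanSetpoint)
  if (is.null(noise)) noise <- numeric(length(u))
  if (is.null(theta0)) theta0 <- wEff * u[1] + r
  E0 <- if (p$Ki > 0) -p$mgh * theta0 / p$Ki else 0
  pendulum_loop(u, du, dt, p$inertia, p$mgh, p$Kp, p$Kd, p$Ki,
                as.integer(dlay), wEff, r, noise, theta0, 0, E0,
                deg2rad(FALL_LIMIT_DEG))
}

#' Verify closed-loop stability
#'
#' Simulates 30 s of the noise-free loop released 1 degree away from its
#' equilibrium lean and requires the deviation to decay to below 20% of the
#' perturbation.  On failure an error reports the dominant oscillation
#' frequency of the growing mode.
#'
#' @param params a [balanceModelParams()] list.
#' @param sampleRate integration rate, Hz.
#' @return invisibly `TRUE` when stable.
#' @export
checkStability <- function(params, sampleRate = 100) {
  n <- 30 * sampleRate
  u <- numeric(n)
  eq <- deg2rad(params$leanSetpoint)
  res <- runLoop(u, u, params, sampleRate, theta0 = eq + deg2rad(1))
  dev <- res$theta - eq
  if (res$fell || max(abs(dev[(n - 5 * sampleRate):n])) > 0.2 * deg2rad(1)) {
    zc <- which(diff(sign(dev)) != 0)
    f <- if (length(zc) > 2) sampleRate / (2 * mean(diff(zc))) else 0
    stop(sprintf(paste0("closed loop is unstable: impulse response does not ",
                        "decay (dominant mode near %.2f Hz)"), f),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Analytic closed-loop frequency response
#'
#' Evaluates the continuous-time transfer function from platform tilt to
#' body (COM) angle,
#' `H(f) = wProp P C / (1 + P C)` at `s = i 2 pi f`, with plant
#' `P(s) = 1 / (J s^2 - m g h)` and controller
#' `C(s) = (Kp + Kd s + Ki / s) exp(-delay s)`.  This is the exact response
#' of the model [simulateSway()] integrates, and serves as the oracle for
#' the empirical FRF estimators.
#'
#' @param params a [balanceModelParams()] list.
#' @param freqs frequencies, Hz (> 0).
#' @return complex vector `H(freqs)`.
#' @examples
#' H <- analyticFRF(balanceModelParams(), c(0.05, 0.25, 1.05))
#' Mod(H); rad2deg <- function(x) x * 180 / pi; rad2deg(Arg(H))
#' @export
analyticFRF <- function(params, freqs) {
  if (any(freqs <= 0)) stop("freqs must be > 0")
  checkStability(params)
  s <- 2i * pi * freqs
  P <- 1 / (params$inertia * s^2 - params$mgh)
  C <- (params$Kp + params$Kd * s + params$Ki / s) * exp(-params$delay * s)
  params$wProp * P * C / (1 + P * C)
}

## internal: effective proprioceptive weight under the optional amplitude
## nonlinearity
effectiveWeight <- function(params, stimulus) {
  w <- params$wProp
  if (params$reweightExponent > 0) {
    pp <- diff(range(tiltAngle(stimulus)))
    if (pp > 1) w <- w * pp^(-params$reweightExponent)
  }
  w
}

## internal: derive markers, COP and COM truth from the pendulum state
assembleChannels <- function(thetaRad, torque, params, sampleRate) {
  n <- length(thetaRad)
  H <- params$bodyHeight; a <- params$anthro; M <- params$bodyMass
  zHip <- a$hipHeightFrac * H
  lTrunk <- (a$shoulderHeightFrac - a$hipHeightFrac) * H
  phi <- if (params$hipAmp > 0)
    deg2rad(params$hipAmp) * sin(2 * pi * params$hipFreq *
                                 (0:(n - 1)) / sampleRate) else numeric(n)
  hip <- zHip * sin(thetaRad)
  shoulder <- hip + lTrunk * sin(thetaRad + phi)
  mLeg <- a$legMassFrac; mHat <- 1 - mLeg
  comX <- mLeg * (a$legComFrac * H) * sin(thetaRad) +
    mHat * (zHip * sin(thetaRad) + (a$hatComAboveHipFrac * H) * sin(thetaRad + phi))
  comAngle <- rad2deg(asin(comX / params$comHeight))
  cop <- -torque / (M * GRAVITY)
  if (params$copNoiseSd > 0)
    cop <- cop + stats::rnorm(n, 0, params$copNoiseSd)
  if (params$markerNoiseSd > 0) {
    hip <- hip + stats::rnorm(n, 0, params$markerNoiseSd)
    shoulder <- shoulder + stats::rnorm(n, 0, params$markerNoiseSd)
  }
  list(hip = hip, shoulder = shoulder, cop = cop, comAngle = comAngle)
}

#' Simulate one sway trial
#'
#' Integrates the delayed closed loop driven by a platform tilt stimulus
#' (fixed-step RK4 at the stimulus sample rate, transport delay as an
#' integer-sample buffer) and assembles a [SwayRecording-class]: platform
#' tilt, the COM-angle truth channel, hip and shoulder marker translations
#' from the two-segment output geometry, and the centre of pressure from
#' the applied ankle torque, `cop_x = -T / (m g)`, plus sensor noise.  The
#' loop starts at its quasi-static equilibrium, so noise-free recordings
#' begin in steady state.  Deterministic given `seed`.
#'
#' @param stimulus a [StimulusSequence-class].
#' @param params a [balanceModelParams()] list.
#' @param seed integer seed for the noise channels (`NULL` uses the current
#'   RNG state).
#' @param subjectId,trialLabel provenance strings.
#' @return a [SwayRecording-class].
#' @examples
#' stim <- buildPRTS(ternaryDesign(), 1.78, nCycles = 2)
#' p <- balanceModelParams(noiseSd = 0, copNoiseSd = 0)
#' rec <- simulateSway(stim, p, seed = 1)
#' @export
simulateSway <- function(stimulus, params, seed = NULL,
                         subjectId = "sim", trialLabel = "trial") {
  stopifnot(is(stimulus, "StimulusSequence"),
            inherits(params, "BalanceModelParams"))
  sr <- sampleRate(stimulus)
  u <- deg2rad(tiltAngle(stimulus))
  du <- deg2rad(tiltVelocity(stimulus))
  n <- length(u)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  noise <- filteredNoise(n, params$noiseSd, params$noiseTau, sr)

  res <- runLoop(u, du, params, sr, wEff = effectiveWeight(params, stimulus),
                 noise = as.numeric(noise))
  if (res$fell)
    stop(sprintf("simulated fall: |COM angle| exceeded %g deg at t = %.2f s",
                 FALL_LIMIT_DEG, (res$fell_at - 1) / sr), call. = FALSE)

  ch <- assembleChannels(res$theta, res$torque, params, sr)
  new("SwayRecording",
      platformTilt = tiltAngle(stimulus), comAngle = ch$comAngle,
      hipX = ch$hip, shoulderX = ch$shoulder, copX = ch$cop,
      sampleRate = sr, subjectId = subjectId, trialLabel = trialLabel)
}

#' Simulate the quasi-static calibration trial
#'
#' Emulates the calibration routine: the subject performs very slow ankle
#' and hip tilt movements on the static platform, so the centre of pressure
#' equals the vertical projection of the COM at every sample (plus sensor
#' noise).  Ankle and hip angles follow slow prescribed sinusoids at
#' incommensurate periods, which keeps hip and shoulder translations
#' linearly independent.
#'
#' @param params a [balanceModelParams()] list.
#' @param duration trial duration, s.
#' @param sampleRate sampling rate, Hz.
#' @param seed integer seed for the sensor noise.
#' @param ankleAmp,hipSwingAmp movement amplitudes, degrees.
#' @param subjectId provenance string.
#' @return a [SwayRecording-class] with platform tilt identically zero and
#'   the COM truth channel filled in.
#' @export
simulateCalibrationTrial <- function(params, duration = 120, sampleRate = 100,
                                     seed = NULL, ankleAmp = 1.5,
                                     hipSwingAmp = 4,
                                     subjectId = "sim") {
  n <- round(duration * sampleRate)
  tt <- (0:(n - 1)) / sampleRate
  theta <- deg2rad(params$leanSetpoint + ankleAmp * sin(2 * pi * tt / 60))
  phi <- deg2rad(hipSwingAmp * sin(2 * pi * tt / 41 + 1))

  H <- params$bodyHeight; a <- params$anthro
  zHip <- a$hipHeightFrac * H
  lTrunk <- (a$shoulderHeightFrac - a$hipHeightFrac) * H
  hip <- zHip * sin(theta)
  shoulder <- hip + lTrunk * sin(theta + phi)
  mLeg <- a$legMassFrac; mHat <- 1 - mLeg
  comX <- mLeg * (a$legComFrac * H) * sin(theta) +
    mHat * (zHip * sin(theta) + (a$hatComAboveHipFrac * H) * sin(theta + phi))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  cop <- comX
  if (params$copNoiseSd > 0) cop <- cop + stats::rnorm(n, 0, params$copNoiseSd)

  new("SwayRecording",
      platformTilt = numeric(n),
      comAngle = rad2deg(asin(comX / params$comHeight)),
      hipX = hip, shoulderX = shoulder, copX = cop,
      sampleRate = sampleRate, subjectId = subjectId,
      trialLabel = "calibration")
}

#' True calibration coefficients of the simulator geometry
#'
#' The two-segment geometry makes the COM translation an exact linear
#' combination of the hip and shoulder marker translations; this returns the
#' coefficients [fitCalibration()] should recover on noise-free data.
#'
#' @param params a [balanceModelParams()] list.
#' @return named vector `c(coefHip, coefShoulder)`.
#' @export
calibrationTruth <- function(params) {
  a <- params$anthro
  mLeg <- a$legMassFrac; mHat <- 1 - mLeg
  B <- mHat * a$hatComAboveHipFrac /
    (a$shoulderHeightFrac - a$hipHeightFrac)
  A <- (mLeg * a$legComFrac + mHat * a$hipHeightFrac) / a$hipHeightFrac - B
  c(coefHip = A, coefShoulder = B)
}

#' Learning-cohort configuration
#'
#' Defines the simulated cohort for the learning phase: cohort size, number
#' of trial repetitions, the across-trial drift of the lean setpoint and of
#' the proprioceptive weight (exponential approach from a start to an end
#' value), and between-subject dispersion.  The defaults emulate the study
#' conditions the analysis chain targets: 19 subjects, 75 trials, forward
#' lean relaxing from 3.3 to 2.4 degrees, and the stimulus-evoked sway power
#' (proportional to the squared weight) shrinking by 33% across the phase
#' while the torque-noise level - hence the non-stimulus sway floor - stays
#' fixed.
#'
#' @param nSubjects,nTrials cohort size and trials per subject.
#' @param leanStart,leanEnd,leanTau lean-setpoint drift: start and end
#'   values (degrees) and exponential time constant (trials).
#' @param wStart,wEnd,wTau proprioceptive-weight drift; the default end
#'   value is `wStart * sqrt(0.67)`.
#' @param drift logical; `FALSE` freezes both parameters at their start
#'   values (null generator).
#' @param subjectSd between-subject SDs: `lean` (degrees, shifts both lean
#'   endpoints), `logKp` (log-normal spread of the stiffness gain),
#'   `w` (additive spread of the weight, truncated to `[0.05, 0.95]`).
#' @param params baseline [balanceModelParams()].
#' @param seed master seed; all per-subject and per-trial randomness derives
#'   from it.
#' @return a configuration list (class `"LearningCohortConfig"`).
#' @export
learningCohortConfig <- function(nSubjects = 19L, nTrials = 75L,
                                 leanStart = 3.3, leanEnd = 2.4, leanTau = 20,
                                 wStart = 0.6, wEnd = 0.6 * sqrt(0.67),
                                 wTau = 20, drift = TRUE,
                                 subjectSd = list(lean = 0.4, logKp = 0.08,
                                                  w = 0.03),
                                 params = balanceModelParams(), seed = 1L) {
  stopifnot(nSubjects >= 1L, nTrials >= 1L)
  if (!drift) { leanEnd <- leanStart; wEnd <- wStart }
  structure(list(nSubjects = as.integer(nSubjects),
                 nTrials = as.integer(nTrials),
                 leanStart = leanStart, leanEnd = leanEnd, leanTau = leanTau,
                 wStart = wStart, wEnd = wEnd, wTau = wTau, drift = drift,
                 subjectSd = subjectSd, params = params,
                 seed = as.integer(seed)),
            class = "LearningCohortConfig")
}

## internal: exponential approach from start to end with time constant tau
driftCurve <- function(start, end, tau, t) end + (start - end) * exp(-t / tau)

#' Simulate a learning cohort
#'
#' Simulates `nTrials` learning-sequence trials for each of `nSubjects`
#' subjects, with per-trial parameter drift (lean setpoint, proprioceptive
#' weight) providing known ground-truth trends for the downstream metric
#' and trend-model recovery.  All randomness derives from the config's
#' master seed.
#'
#' @param config a [learningCohortConfig()] list.
#' @param stimulus the learning stimulus ([buildLearningSequence()]).
#' @return list of [SwayRecording-class], ordered subject-major; the
#'   attribute `"truth"` carries a data.frame of the per-trial parameter
#'   values (`subject`, `trial` 0-based, `lean_deg`, `w_prop`).
#' @export
simulateLearningCohort <- function(config, stimulus = buildLearningSequence()) {
  stopifnot(inherits(config, "LearningCohortConfig"))
  p0 <- config$params
  nS <- config$nSubjects; nT <- config$nTrials
  seeds <- deriveSeeds(config$seed, nS * (nT + 1L))
  recordings <- vector("list", nS * nT)
  truth <- data.frame(subject = character(nS * nT),
                      trial = integer(nS * nT),
                      lean_deg = numeric(nS * nT), w_prop = numeric(nS * nT))
  idx <- 0L
  for (i in seq_len(nS)) {
    sid <- sprintf("S%02d", i)
    ## subject-level dispersion
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seeds[(i - 1L) * (nT + 1L) + 1L])
    dLean <- stats::rnorm(1, 0, config$subjectSd$lean)
    kpFac <- exp(stats::rnorm(1, 0, config$subjectSd$logKp))
    dW <- stats::rnorm(1, 0, config$subjectSd$w)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

    pS <- p0
    pS$Kp <- p0$Kp * kpFac
    for (t in seq_len(nT) - 1L) {
      lean <- driftCurve(config$leanStart, config$leanEnd, config$leanTau, t) +
        dLean
      w <- driftCurve(config$wStart, config$wEnd, config$wTau, t) + dW
      w <- min(max(w, 0.05), 0.95)
      pT <- pS
      ## the configured lean trajectory is the target measured body lean;
      ## the platform's mean tilt pulls the equilibrium by w * mean(u), so
      ## the controller setpoint is back-computed to keep the measured
      ## starting position on the configured curve
      pT$leanSetpoint <- lean - w * mean(tiltAngle(stimulus))
      pT$wProp <- w
      idx <- idx + 1L
      recordings[[idx]] <- simulateSway(
        stimulus, pT, seed = seeds[(i - 1L) * (nT + 1L) + 1L + t + 1L],
        subjectId = sid, trialLabel = sprintf("learning%03d", t))
      truth$subject[idx] <- sid
      truth$trial[idx] <- t
      truth$lean_deg[idx] <- lean
      truth$w_prop[idx] <- w
    }
  }
  attr(recordings, "truth") <- truth
  recordings
}
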