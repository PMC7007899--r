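## Per-trial analysis of the 8-s learning sequences: detrending, spectral
## partitioning, feedback score, and gain/phase at the stimulus frequencies.

LEARNING_DURATION <- 8          # s
LEARNING_DF <- 1 / LEARNING_DURATION   # 0.125 Hz spectral resolution
LEARNING_NBINS <- 16L           # bins 0.125 .. 2 Hz
STIM_BINS <- c(8L, 10L)         # 1.0 and 1.25 Hz
LOW_BINS <- c(1L, 2L)           # 0.125 and 0.250 Hz

#' Detrend one learning trial
#'
#' Fits a least-squares line to the COM sway trajectory of one 8-s trial and
#' removes it.  The intercept (the value of the line at `t = 0`) is the
#' starting position; the slope is the linear drift.
#'
#' @param trace COM sway trace, degrees.
#' @param sampleRate sampling rate, Hz; the trace must be exactly
#'   `8 * sampleRate` samples long.
#' @return list with `intercept` (deg), `slope` (deg/s) and `residual`
#'   (detrended trace).
#' @examples
#' sr <- 100; t <- (0:(8 * sr - 1)) / sr
#' detrendTrial(3.3 - 0.05 * t, sr)[c("intercept", "slope")]
#' @export
detrendTrial <- function(trace, sampleRate = 100) {
  n <- round(LEARNING_DURATION * sampleRate)
  if (length(trace) != n)
    stop(sprintf("trace must be %g s long (%d samples), got %d",
                 LEARNING_DURATION, n, length(trace)), call. = FALSE)
  tt <- (0:(n - 1)) / sampleRate
  fit <- stats::lm.fit(cbind(1, tt), trace)
  list(intercept = unname(fit$coefficients[1L]),
       slope = unname(fit$coefficients[2L]),
       residual = unname(fit$residuals))
}

#' Single-sided amplitude spectrum of a detrended trial
#'
#' Discrete Fourier amplitudes scaled so that a time-domain sine of
#' amplitude `a` appears as `a` in its bin (`2 |X_k| / N`), at the 0.125-Hz
#' resolution of the 8-s window, bins 0.125 to 2 Hz.
#'
#' @param residual detrended 8-s trace, degrees.
#' @param sampleRate sampling rate, Hz.
#' @return named numeric vector of 16 amplitudes (deg); names are
#'   frequencies in Hz.
#' @export
amplitudeSpectrum <- function(residual, sampleRate = 100) {
  n <- round(LEARNING_DURATION * sampleRate)
  if (length(residual) != n)
    stop(sprintf("trace must be %d samples long", n), call. = FALSE)
  amps <- 2 * Mod(stats::fft(residual))[1L + seq_len(LEARNING_NBINS)] / n
  names(amps) <- format(seq_len(LEARNING_NBINS) * LEARNING_DF)
  amps
}

#' Partition spectral sway power
#'
#' Splits the 16-bin amplitude spectrum into stimulus-frequency power
#' (1.0 and 1.25 Hz), non-stimulus low-frequency power (0.125 and 0.250 Hz,
#' the bins that dominate spontaneous sway), and the remaining high-frequency
#' power.  Power is the sum of squared amplitudes per group, so the three
#' parts add up to the full-spectrum power exactly.
#'
#' @param spectrum 16-bin amplitude spectrum from [amplitudeSpectrum()].
#' @return named list `full`, `stim`, `low`, `high` (deg^2).
#' @export
partitionPSD <- function(spectrum) {
  if (length(spectrum) != LEARNING_NBINS)
    stop(sprintf("expected a %d-bin spectrum", LEARNING_NBINS), call. = FALSE)
  p <- spectrum^2
  stim <- sum(p[STIM_BINS]); low <- sum(p[LOW_BINS])
  high <- sum(p[-c(STIM_BINS, LOW_BINS)])
  list(full = stim + low + high, stim = stim, low = low, high = high)
}

#' Feedback score of one learning trial
#'
#' The composite score reported to subjects after each trial:
#' `fb = sum(|amplitudes|) * 100 + |slope| * 1000`, summing the spectral
#' sway amplitudes over the 0.125-2 Hz bins.  When one component exceeds
#' 70% of the score (strictly), the score is flagged as sway- or
#' drift-dominated.
#'
#' @param spectrum 16-bin amplitude spectrum, degrees.
#' @param slope linear drift, deg/s.
#' @return list with `fb`, the components `sway` and `drift`, and
#'   `dominance` (`"sway"`, `"drift"` or `NA`).
#' @examples
#' sp <- numeric(16); sp[8] <- 0.5
#' feedbackScore(sp, 0)$fb          # 50
#' feedbackScore(numeric(16), 0.2)$fb   # 200
#' @export
feedbackScore <- function(spectrum, slope) {
  if (length(spectrum) != LEARNING_NBINS)
    stop(sprintf("expected a %d-bin spectrum", LEARNING_NBINS), call. = FALSE)
  sway <- sum(abs(spectrum)) * 100
  drift <- abs(slope) * 1000
  fb <- sway + drift
  dominance <- if (fb > 0 && sway / fb > 0.7) "sway"
               else if (fb > 0 && drift / fb > 0.7) "drift"
               else NA_character_
  list(fb = fb, sway = sway, drift = drift, dominance = dominance)
}

#' Gain and phase at the stimulus frequencies
#'
#' Complex spectral ratio of the (detrended) COM trace to the stimulus at
#' 1.0 and 1.25 Hz, aggregated into single gain and phase values by
#' averaging with the stimulus amplitudes as weights (phases unwrapped so
#' the two angles sit in the same branch; lag negative).
#'
#' @param comTrace COM sway trace, degrees (8 s).
#' @param stimulusTrace platform tilt trace, degrees (8 s, same rate).
#' @param sampleRate sampling rate, Hz.
#' @param perFrequency return the per-frequency values instead of the
#'   amplitude-weighted aggregate.
#' @return list with `gain` and `phase` (degrees); with
#'   `perFrequency = TRUE`, vectors of length 2 plus `freqs`.
#' @export
stimGainPhase <- function(comTrace, stimulusTrace, sampleRate = 100,
                          perFrequency = FALSE) {
  n <- round(LEARNING_DURATION * sampleRate)
  if (length(comTrace) != n || length(stimulusTrace) != n)
    stop(sprintf("both traces must be %d samples long", n), call. = FALSE)
  Xc <- stats::fft(comTrace)[STIM_BINS + 1L]
  Xs <- stats::fft(stimulusTrace)[STIM_BINS + 1L]
  stimAmp <- 2 * Mod(Xs) / n
  if (any(stimAmp < 1e-12))
    stop("stimulus carries no energy at a stimulus frequency", call. = FALSE)
  ratio <- Xc / Xs
  gains <- Mod(ratio)
  phases <- unwrapDeg(wrapDeg(rad2deg(Arg(ratio))))
  if (perFrequency)
    return(list(freqs = STIM_BINS * LEARNING_DF, gain = gains,
                phase = phases))
  w <- stimAmp / sum(stimAmp)
  list(gain = sum(w * gains), phase = sum(w * phases))
}

#' All nine metrics of one learning trial
#'
#' Runs the full per-trial pipeline: linear detrending (starting position
#' and drift), amplitude spectrum, spectral power partition, feedback score,
#' and gain/phase at the stimulus frequencies.
#'
#' @param rec a [SwayRecording-class] of one 8-s learning trial.
#' @param stimulus the learning [StimulusSequence-class].
#' @param response optional response trace, degrees (defaults to the
#'   recording's COM channel; pass a calibrated trace for measured data).
#' @return one-row data.frame with columns `subject`, `trial` (0-based,
#'   parsed from the trial label when possible), `full_psd`, `stim_psd`,
#'   `low_psd`, `high_psd` (deg^2), `drift_slope` (deg/s),
#'   `starting_position` (deg), `fb`, `fb_dominance`, `gain_stim`,
#'   `phase_stim` (deg).
#' @export
learningTrialMetrics <- function(rec, stimulus, response = NULL) {
  stopifnot(is(rec, "SwayRecording"), is(stimulus, "StimulusSequence"))
  sr <- sampleRate(rec)
  if (is.null(response)) response <- comAngle(rec)
  det <- detrendTrial(response, sr)
  sp <- amplitudeSpectrum(det$residual, sr)
  parts <- partitionPSD(sp)
  fb <- feedbackScore(sp, det$slope)
  gp <- stimGainPhase(det$residual, tiltAngle(stimulus), sr)
  lbl <- trialLabel(rec)
  tno <- suppressWarnings(as.integer(sub("\\D*", "", lbl)))
  data.frame(subject = subjectId(rec), trial = tno,
             full_psd = parts$full, stim_psd = parts$stim,
             low_psd = parts$low, high_psd = parts$high,
             drift_slope = det$slope, starting_position = det$intercept,
             fb = fb$fb, fb_dominance = fb$dominance,
             gain_stim = gp$gain, phase_stim = gp$phase,
             stringsAsFactors = FALSE)
}

#' Metrics table of a learning cohort
#'
#' Applies [learningTrialMetrics()] to every recording and binds the rows.
#'
#' @param recordings list of [SwayRecording-class] (e.g. from
#'   [simulateLearningCohort()]).
#' @param stimulus the learning [StimulusSequence-class].
#' @param responses optional list of response traces matching `recordings`.
#' @return data.frame with one row per (subject, trial).
#' @export
learningMetricsTable <- function(recordings, stimulus, responses = NULL) {
  rows <- lapply(seq_along(recordings), function(i)
    learningTrialMetrics(recordings[[i]], stimulus,
                         response = if (is.null(responses)) NULL
                                    else responses[[i]]))
  do.call(rbind, rows)
}
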