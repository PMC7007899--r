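## Cycle-segmented frequency-response-function and coherence estimation for
## the pseudo-random trials.

#' Segment a recording into stimulus/response cycles
#'
#' Cuts a recording into consecutive cycles of `cycleDuration` seconds,
#' optionally discarding the first cycle to avoid the transient response.
#' The response defaults to the recording's COM truth channel; pass the
#' calibrated COM trace ([applyCalibration()]) to analyse measured data.
#'
#' @param rec a [SwayRecording-class].
#' @param cycleDuration cycle duration, s; the recording must contain a
#'   whole number of cycles.
#' @param discardFirst drop the first cycle (transient).
#' @param response response trace in degrees (defaults to `comAngle(rec)`).
#' @return a [CycleSet-class] with provenance (`subject`, `trial`, `cycle`).
#' @examples
#' stim <- buildPRTS(ternaryDesign(), 1.78, nCycles = 3)
#' rec <- simulateSway(stim, balanceModelParams(noiseSd = 0, copNoiseSd = 0))
#' nCycles(segmentCycles(rec, 20))        # 2 (first discarded)
#' @export
segmentCycles <- function(rec, cycleDuration, discardFirst = TRUE,
                          response = NULL) {
  stopifnot(is(rec, "SwayRecording"))
  sr <- sampleRate(rec)
  if (is.null(response)) response <- comAngle(rec)
  n <- recordingLength(rec)
  if (length(response) != n)
    stop("response trace must match the recording length")
  if (all(is.na(response)))
    stop("recording has no COM channel; supply a calibrated response trace")
  nPer <- cycleDuration * sr
  if (abs(nPer - round(nPer)) > 1e-9)
    stop("cycleDuration must correspond to a whole number of samples")
  nPer <- round(nPer)
  k <- n / nPer
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf(paste0("recording does not contain a whole number of ",
                        "cycles: %.3f s left over"),
                 (n - floor(k) * nPer) / sr), call. = FALSE)
  k <- round(k)
  stim <- matrix(platformTilt(rec), nrow = k, ncol = nPer, byrow = TRUE)
  resp <- matrix(response, nrow = k, ncol = nPer, byrow = TRUE)
  keep <- if (discardFirst) seq_len(k)[-1L] else seq_len(k)
  if (!length(keep)) stop("no cycles left after discarding the first")
  cycleSet(stim[keep, , drop = FALSE], resp[keep, , drop = FALSE],
           cycleDuration, sr,
           provenance = data.frame(subject = subjectId(rec),
                                   trial = trialLabel(rec), cycle = keep))
}

#' Pool cycle sets
#'
#' Row-binds cycle sets from several recordings (e.g. all subjects of one
#' stimulus condition) into the common cycle pool used for averaging and
#' bootstrap resampling.
#'
#' @param ... [CycleSet-class] objects with identical timing.
#' @return a pooled [CycleSet-class].
#' @export
combineCycleSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "CycleSet"))
    sets <- sets[[1L]]
  cd <- unique(vapply(sets, cycleDuration, numeric(1)))
  sr <- unique(vapply(sets, sampleRate, numeric(1)))
  if (length(cd) != 1L || length(sr) != 1L)
    stop("cycle sets have inconsistent timing")
  out <- do.call(rbind, sets)
  rownames(out) <- sprintf("cycle%03d", seq_len(nrow(out)))
  metadata(out) <- list(cycleDuration = cd, sampleRate = sr)
  new("CycleSet", out)
}

## internal: per-cycle complex spectra at integer harmonic bins
cycleSpectra <- function(mat, bins) {
  sp <- stats::mvfft(t(mat))           # sample x cycle
  t(sp[bins + 1L, , drop = FALSE])     # cycle x bin
}

## internal: map excited frequencies to integer harmonic indices
harmonicBins <- function(freqs, cycleDur) {
  k <- freqs * cycleDur
  if (any(abs(k - round(k)) > 1e-6))
    stop("requested frequencies are not harmonics of the cycle")
  as.integer(round(k))
}

#' Estimate the frequency response function
#'
#' Computes per-cycle discrete Fourier transforms of stimulus and response,
#' forms the per-cycle spectral ratio at the excited harmonics, and averages
#' the complex ratios across cycles.  Gain is the modulus of the averaged
#' FRF; phase is its argument, unwrapped across frequency, in degrees with
#' lag negative.  Frequencies at which the stimulus carries no energy are
#' dropped with a warning.
#'
#' @param cs a [CycleSet-class] (>= 2 cycles).
#' @param excited excited frequencies, Hz (harmonics of the cycle).
#' @param withCoherence also fill the coherence slot via
#'   [estimateCoherence()].
#' @return a [FrequencyResponse-class].
#' @export
estimateFRF <- function(cs, excited, withCoherence = FALSE) {
  stopifnot(is(cs, "CycleSet"))
  if (nCycles(cs) < 2L) stop("FRF estimation needs at least 2 cycles")
  bins <- harmonicBins(excited, cycleDuration(cs))
  S <- cycleSpectra(stimulusCycles(cs), bins)
  R <- cycleSpectra(responseCycles(cs), bins)
  stimAmp <- colMeans(Mod(S))
  dead <- stimAmp < 1e-12 * max(stimAmp)
  if (any(dead)) {
    warning(sprintf("dropping %d frequencies with zero stimulus amplitude: %s",
                    sum(dead), paste(excited[dead], collapse = ", ")))
    excited <- excited[!dead]; S <- S[, !dead, drop = FALSE]
    R <- R[, !dead, drop = FALSE]
  }
  frf <- colMeans(R / S)
  phase <- unwrapDeg(wrapDeg(rad2deg(Arg(frf))))
  coh <- if (withCoherence) estimateCoherence(cs, excited)
         else rep(NA_real_, length(excited))
  new("FrequencyResponse", freqs = excited, gain = Mod(frf), phase = phase,
      coherence = coh, nCycles = nCycles(cs), ci = list())
}

#' Estimate magnitude-squared coherence
#'
#' Coherence is the squared cross-power spectrum between stimulus and
#' response divided by the product of the two auto-power spectra, each
#' averaged across cycles: 1 means fully stimulus-locked sway, values near
#' `1/nCycles` indicate sway unrelated to the stimulus.  A single cycle is
#' refused (its coherence is identically 1).
#'
#' @param cs a [CycleSet-class] (>= 2 cycles).
#' @param excited excited frequencies, Hz.
#' @return numeric coherence per frequency, in `[0, 1]`.
#' @export
estimateCoherence <- function(cs, excited) {
  stopifnot(is(cs, "CycleSet"))
  if (nCycles(cs) < 2L)
    stop("coherence from a single cycle is identically 1 and refused")
  bins <- harmonicBins(excited, cycleDuration(cs))
  S <- cycleSpectra(stimulusCycles(cs), bins)
  R <- cycleSpectra(responseCycles(cs), bins)
  cross <- colMeans(Conj(S) * R)
  pS <- colMeans(Mod(S)^2)
  pR <- colMeans(Mod(R)^2)
  pmin(1, Mod(cross)^2 / (pS * pR))
}

#' Cycle-averaged time-domain responses
#'
#' Averages stimulus and response across cycles with the per-trial offset
#' retained (the offset carries the mean body lean).
#'
#' @param cs a [CycleSet-class].
#' @return list with numeric vectors `stimulus` and `response` (degrees)
#'   and `time` (seconds).
#' @export
cycleMean <- function(cs) {
  stopifnot(is(cs, "CycleSet"))
  list(time = (seq_len(ncol(cs)) - 1L) / sampleRate(cs),
       stimulus = colMeans(stimulusCycles(cs)),
       response = colMeans(responseCycles(cs)))
}

#' Band-average a frequency response for display
#'
#' Averages gain, phase and coherence within logarithmically spaced
#' frequency bands (the usual display of tilt-posturography Bode plots).
#' The raw per-harmonic object is left untouched.
#'
#' @param fr a [FrequencyResponse-class].
#' @param nBands number of logarithmic bands.
#' @return data.frame with one row per non-empty band.
#' @export
bandAverage <- function(fr, nBands = 11L) {
  stopifnot(is(fr, "FrequencyResponse"))
  f <- fr@freqs
  edges <- exp(seq(log(min(f) * 0.999), log(max(f) * 1.001),
                   length.out = nBands + 1L))
  band <- cut(f, edges, include.lowest = TRUE)
  agg <- function(x) tapply(x, band, mean)
  out <- data.frame(freq_hz = as.numeric(agg(f)), gain = as.numeric(agg(fr@gain)),
                    phase_deg = as.numeric(agg(fr@phase)),
                    coherence = as.numeric(agg(fr@coherence)))
  out[!is.na(out$freq_hz), , drop = FALSE]
}
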