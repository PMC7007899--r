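#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
NULL

## ---------------------------------------------------------------------------
## TernaryDesign
## ---------------------------------------------------------------------------

#' Pseudo-random ternary sequence design
#'
#' Describes a maximal-length ternary shift-register recurrence over the
#' 3-element field together with the mapping of field symbols onto platform
#' velocity signs and the timing of the velocity staircase.  The generated
#' symbol sequence has period `3^m - 1`, balanced numbers of `+1` and `-1`
#' symbols (zero net platform displacement per cycle) and a flat amplitude
#' spectrum across its non-null harmonics.
#'
#' @slot registerOrder degree m of the recurrence (period `3^m - 1`).
#' @slot taps integer coefficients of the recurrence
#'   `s_n = taps[1] s_(n-1) + ... + taps[m] s_(n-m) (mod 3)`.
#' @slot symbolMap integer vector of length 3 mapping field symbols
#'   `(0, 1, 2)` to velocity signs in `{-1, 0, +1}`.
#' @slot stepDuration duration of one velocity step, seconds.
#'
#' @seealso [ternaryDesign()], [generateTernarySymbols()], [buildPRTS()]
#' @export
setClass("TernaryDesign",
  representation(registerOrder = "integer", taps = "integer",
                 symbolMap = "integer", stepDuration = "numeric"))

setValidity("TernaryDesign", function(object) {
  m <- object@registerOrder
  if (length(m) != 1L || m < 2L) return("registerOrder must be a single integer >= 2")
  if (length(object@taps) != m) return("need exactly registerOrder taps")
  if (!all(object@taps %in% 0:2)) return("taps must be coefficients in {0,1,2}")
  if (all(object@taps[m] == 0L)) return("last tap must be nonzero (degenerate register)")
  sm <- object@symbolMap
  if (length(sm) != 3L || !setequal(sm, c(-1L, 0L, 1L)))
    return("symbolMap must be a permutation of (-1, 0, 1)")
  if (sm[1] != 0L) return("field symbol 0 must map to velocity sign 0")
  if (object@stepDuration <= 0) return("stepDuration must be positive")
  TRUE
})

#' Cycle duration implied by a design
#'
#' @param object a [TernaryDesign-class] or [StimulusSequence-class].
#' @return cycle duration in seconds.
#' @export
setGeneric("cycleDuration", function(object) standardGeneric("cycleDuration"))

#' @rdname cycleDuration
#' @export
setMethod("cycleDuration", "TernaryDesign", function(object)
  object@stepDuration * (3^object@registerOrder - 1))

setMethod("show", "TernaryDesign", function(object) {
  cat("TernaryDesign: m =", object@registerOrder,
      " period =", 3^object@registerOrder - 1, "steps\n")
  cat("  taps:", paste(object@taps, collapse = " "),
      "  symbol map (0,1,2) ->", paste(object@symbolMap, collapse = " "), "\n")
  cat("  step", object@stepDuration, "s, cycle", cycleDuration(object), "s\n")
})

## ---------------------------------------------------------------------------
## StimulusSequence
## ---------------------------------------------------------------------------

#' Platform tilt stimulus
#'
#' A sampled platform tilt-angle trace in degrees (toes-up positive) with its
#' cycle structure and the list of excited harmonics.  The `velocity` slot
#' holds the tilt velocity sampled at sample midpoints, the convention the
#' closed-loop simulator's derivative feedthrough expects (exact for the
#' piecewise-constant PRTS staircase).
#'
#' @slot samples tilt angle trace, degrees, toes-up positive.
#' @slot velocity tilt velocity at sample midpoints, deg/s.
#' @slot sampleRate sampling rate, Hz.
#' @slot cycleDuration duration of one cycle, seconds.
#' @slot nCycles number of concatenated cycles.
#' @slot excitedFrequencies harmonics carrying stimulus energy, Hz.
#' @slot label one of `"pp1"`, `"pp2"`, `"pp4"`, `"warmup"`, `"learning"`.
#' @slot velocityMagnitude nonzero step velocity, deg/s (PRTS only, else NA).
#' @slot config generator configuration (taps, symbol map, solver output, ...).
#' @export
setClass("StimulusSequence",
  representation(samples = "numeric", velocity = "numeric",
                 sampleRate = "numeric", cycleDuration = "numeric",
                 nCycles = "integer", excitedFrequencies = "numeric",
                 label = "character", velocityMagnitude = "numeric",
                 config = "list"))

setValidity("StimulusSequence", function(object) {
  expect <- object@sampleRate * object@cycleDuration * object@nCycles
  if (abs(length(object@samples) - expect) > 1)
    return(sprintf("trace length %d does not match sampleRate*cycleDuration*nCycles = %g",
                   length(object@samples), expect))
  if (length(object@velocity) != length(object@samples))
    return("velocity and samples must have equal length")
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  if (object@nCycles < 1L) return("nCycles must be >= 1")
  if (!object@label %in% c("pp1", "pp2", "pp4", "warmup", "learning", "custom"))
    return("unknown label")
  TRUE
})

#' @rdname cycleDuration
#' @export
setMethod("cycleDuration", "StimulusSequence", function(object) object@cycleDuration)

#' Number of cycles
#' @param object a [StimulusSequence-class] or [CycleSet-class].
#' @return integer cycle count.
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))

#' @rdname nCycles
#' @export
setMethod("nCycles", "StimulusSequence", function(object) object@nCycles)

#' Sampling rate accessor
#' @param object an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "StimulusSequence", function(object) object@sampleRate)

#' Tilt angle trace accessor
#' @param object a [StimulusSequence-class].
#' @return numeric tilt angle trace, degrees.
#' @export
setGeneric("tiltAngle", function(object) standardGeneric("tiltAngle"))

#' @rdname tiltAngle
#' @export
setMethod("tiltAngle", "StimulusSequence", function(object) object@samples)

#' Tilt velocity trace accessor (sample midpoints)
#' @param object a [StimulusSequence-class].
#' @return numeric tilt velocity trace, deg/s.
#' @export
setGeneric("tiltVelocity", function(object) standardGeneric("tiltVelocity"))

#' @rdname tiltVelocity
#' @export
setMethod("tiltVelocity", "StimulusSequence", function(object) object@velocity)

#' Excited harmonics accessor
#' @param object a [StimulusSequence-class].
#' @return numeric vector of excited frequencies, Hz.
#' @export
setGeneric("excitedFrequencies", function(object) standardGeneric("excitedFrequencies"))

#' @rdname excitedFrequencies
#' @export
setMethod("excitedFrequencies", "StimulusSequence", function(object)
  object@excitedFrequencies)

#' Stimulus label accessor
#' @param object a [StimulusSequence-class].
#' @return character label.
#' @export
setGeneric("stimulusLabel", function(object) standardGeneric("stimulusLabel"))

#' @rdname stimulusLabel
#' @export
setMethod("stimulusLabel", "StimulusSequence", function(object) object@label)

setMethod("show", "StimulusSequence", function(object) {
  cat(sprintf("StimulusSequence '%s': %d x %.4g s cycles at %g Hz\n",
              object@label, object@nCycles, object@cycleDuration,
              object@sampleRate))
  cat(sprintf("  peak-to-peak %.3f deg; %d excited frequencies (%.3g..%.3g Hz)\n",
              diff(range(object@samples)), length(object@excitedFrequencies),
              min(object@excitedFrequencies), max(object@excitedFrequencies)))
})

## ---------------------------------------------------------------------------
## SwayRecording
## ---------------------------------------------------------------------------

#' One trial of synchronized posturography traces
#'
#' Platform tilt, hip and shoulder marker translations, centre of pressure,
#' and (for simulated recordings) the true centre-of-mass angle, all sampled
#' at a common rate.  Angles are degrees (toes-up / forward-lean positive),
#' translations metres.
#'
#' @slot platformTilt platform tilt trace, degrees.
#' @slot comAngle true COM angle trace, degrees (`NA` when unknown).
#' @slot hipX,shoulderX anterior-posterior marker translations, metres.
#' @slot copX centre-of-pressure position, metres.
#' @slot sampleRate sampling rate, Hz.
#' @slot subjectId,trialLabel provenance identifiers.
#' @export
setClass("SwayRecording",
  representation(platformTilt = "numeric", comAngle = "numeric",
                 hipX = "numeric", shoulderX = "numeric", copX = "numeric",
                 sampleRate = "numeric", subjectId = "character",
                 trialLabel = "character"))

setValidity("SwayRecording", function(object) {
  n <- length(object@platformTilt)
  lens <- c(length(object@comAngle), length(object@hipX),
            length(object@shoulderX), length(object@copX))
  if (!all(lens == n)) return("all channels must have the same length")
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  TRUE
})

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "SwayRecording", function(object) object@sampleRate)

#' Channel accessors for sway recordings
#'
#' @param object a [SwayRecording-class].
#' @return the requested channel as a numeric vector (`recordingLength`
#'   returns the number of samples).
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
setGeneric("platformTilt", function(object) standardGeneric("platformTilt"))
#' @rdname recording-accessors
#' @export
setMethod("platformTilt", "SwayRecording", function(object) object@platformTilt)

#' @rdname recording-accessors
#' @export
setGeneric("comAngle", function(object) standardGeneric("comAngle"))
#' @rdname recording-accessors
#' @export
setMethod("comAngle", "SwayRecording", function(object) object@comAngle)

#' @rdname recording-accessors
#' @export
setGeneric("hipX", function(object) standardGeneric("hipX"))
#' @rdname recording-accessors
#' @export
setMethod("hipX", "SwayRecording", function(object) object@hipX)

#' @rdname recording-accessors
#' @export
setGeneric("shoulderX", function(object) standardGeneric("shoulderX"))
#' @rdname recording-accessors
#' @export
setMethod("shoulderX", "SwayRecording", function(object) object@shoulderX)

#' @rdname recording-accessors
#' @export
setGeneric("copX", function(object) standardGeneric("copX"))
#' @rdname recording-accessors
#' @export
setMethod("copX", "SwayRecording", function(object) object@copX)

#' @rdname recording-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname recording-accessors
#' @export
setMethod("subjectId", "SwayRecording", function(object) object@subjectId)

#' @rdname recording-accessors
#' @export
setGeneric("trialLabel", function(object) standardGeneric("trialLabel"))
#' @rdname recording-accessors
#' @export
setMethod("trialLabel", "SwayRecording", function(object) object@trialLabel)

#' @rdname recording-accessors
#' @export
setGeneric("recordingLength", function(object) standardGeneric("recordingLength"))
#' @rdname recording-accessors
#' @export
setMethod("recordingLength", "SwayRecording", function(object)
  length(object@platformTilt))

setMethod("show", "SwayRecording", function(object) {
  n <- recordingLength(object)
  cat(sprintf("SwayRecording %s/%s: %d samples (%.4g s at %g Hz)\n",
              object@subjectId, object@trialLabel, n,
              n / object@sampleRate, object@sampleRate))
  cat(sprintf("  tilt range [%.2f, %.2f] deg; COM truth %s\n",
              min(object@platformTilt), max(object@platformTilt),
              if (all(is.na(object@comAngle))) "absent" else "present"))
})

## ---------------------------------------------------------------------------
## CycleSet (SummarizedExperiment of cycle x sample matrices)
## ---------------------------------------------------------------------------

#' Paired stimulus/response cycle matrices
#'
#' Stores one row per stimulus cycle with matched stimulus and response
#' assays (cycle x sample, degrees), cycle provenance in `rowData`
#' (`subject`, `trial`, `cycle`), and timing in `metadata`.  Extends
#' `SummarizedExperiment`, so row subsetting, `rbind` and accessors work as
#' usual; rows are the resampling unit of the cycle bootstrap.
#'
#' @seealso [cycleSet()], [segmentCycles()], [estimateFRF()],
#'   [bootstrapStatistic()]
#' @export
setClass("CycleSet", contains = "SummarizedExperiment")

setValidity("CycleSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("stimulus", "response") %in% an))
    return("assays 'stimulus' and 'response' are required")
  md <- metadata(object)
  if (is.null(md$cycleDuration) || is.null(md$sampleRate))
    return("metadata must carry cycleDuration and sampleRate")
  expect <- md$cycleDuration * md$sampleRate
  if (abs(ncol(object) - expect) > 1)
    return(sprintf("row length %d does not equal cycleDuration*sampleRate = %g",
                   ncol(object), expect))
  TRUE
})

#' Construct a CycleSet
#'
#' @param stimulus,response numeric matrices (cycle x sample), degrees.
#' @param cycleDuration cycle duration, seconds.
#' @param sampleRate sampling rate, Hz.
#' @param provenance optional data.frame with one row per cycle (columns
#'   such as `subject`, `trial`, `cycle`).
#' @return a [CycleSet-class].
#' @export
cycleSet <- function(stimulus, response, cycleDuration, sampleRate,
                     provenance = NULL) {
  stimulus <- as.matrix(stimulus); response <- as.matrix(response)
  if (!identical(dim(stimulus), dim(response)))
    stop("stimulus and response cycle matrices must have identical dimensions")
  if (is.null(provenance))
    provenance <- data.frame(subject = NA_character_, trial = NA_character_,
                             cycle = seq_len(nrow(stimulus)))
  rn <- sprintf("cycle%03d", seq_len(nrow(stimulus)))
  dimnames(stimulus) <- dimnames(response) <- list(rn, NULL)
  se <- SummarizedExperiment(
    assays = SimpleList(stimulus = stimulus, response = response),
    rowData = DataFrame(provenance))
  metadata(se) <- list(cycleDuration = cycleDuration, sampleRate = sampleRate)
  new("CycleSet", se)
}

#' @rdname nCycles
#' @export
setMethod("nCycles", "CycleSet", function(object) nrow(object))

#' @rdname cycleDuration
#' @export
setMethod("cycleDuration", "CycleSet", function(object)
  metadata(object)$cycleDuration)

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "CycleSet", function(object) metadata(object)$sampleRate)

#' Cycle matrix accessors
#' @param object a [CycleSet-class].
#' @return numeric matrix (cycle x sample), degrees.
#' @export
setGeneric("stimulusCycles", function(object) standardGeneric("stimulusCycles"))
#' @rdname stimulusCycles
#' @export
setMethod("stimulusCycles", "CycleSet", function(object)
  assay(object, "stimulus"))

#' @rdname stimulusCycles
#' @export
setGeneric("responseCycles", function(object) standardGeneric("responseCycles"))
#' @rdname stimulusCycles
#' @export
setMethod("responseCycles", "CycleSet", function(object)
  assay(object, "response"))

setMethod("show", "CycleSet", function(object) {
  cat(sprintf("CycleSet: %d cycles x %d samples (%g s at %g Hz)\n",
              nrow(object), ncol(object), cycleDuration(object),
              sampleRate(object)))
  subj <- unique(rowData(object)$subject)
  cat(sprintf("  %d subject(s)\n", length(subj[!is.na(subj)])))
})

## ---------------------------------------------------------------------------
## FrequencyResponse
## ---------------------------------------------------------------------------

#' Frequency response function with coherence
#'
#' Per-frequency gain (dimensionless amplitude ratio), phase (degrees, lag
#' negative, unwrapped) and magnitude-squared coherence, with optional
#' bootstrap confidence bounds stored as a named list of two-column
#' (lower, upper) matrices.
#'
#' @slot freqs excited frequencies, Hz.
#' @slot gain,phase,coherence per-frequency estimates.
#' @slot nCycles number of cycles averaged.
#' @slot ci named list of confidence-bound matrices (possibly empty).
#' @export
setClass("FrequencyResponse",
  representation(freqs = "numeric", gain = "numeric", phase = "numeric",
                 coherence = "numeric", nCycles = "integer", ci = "list"))

setValidity("FrequencyResponse", function(object) {
  p <- length(object@freqs)
  if (length(object@gain) != p || length(object@phase) != p)
    return("gain and phase must match freqs in length")
  if (length(object@coherence) != p)
    return("coherence must match freqs in length (use NA when not computed)")
  if (any(object@gain < 0, na.rm = TRUE)) return("gain must be >= 0")
  coh <- object@coherence
  if (any(coh < -1e-9 | coh > 1 + 1e-9, na.rm = TRUE))
    return("coherence must lie in [0, 1]")
  TRUE
})

#' @rdname nCycles
#' @export
setMethod("nCycles", "FrequencyResponse", function(object) object@nCycles)

#' Tabulate a frequency response
#'
#' @param x a [FrequencyResponse-class].
#' @param ... unused.
#' @return data.frame with columns `freq_hz`, `gain`, `phase_deg`,
#'   `coherence`, plus `*_lo`/`*_hi` bounds when present.
#' @export
setMethod("as.data.frame", "FrequencyResponse", function(x, ...) {
  out <- data.frame(freq_hz = x@freqs, gain = x@gain, phase_deg = x@phase,
                    coherence = x@coherence)
  for (nm in names(x@ci)) {
    out[[paste0(nm, "_lo")]] <- x@ci[[nm]][, 1]
    out[[paste0(nm, "_hi")]] <- x@ci[[nm]][, 2]
  }
  out
})

setMethod("show", "FrequencyResponse", function(object) {
  cat(sprintf("FrequencyResponse: %d frequencies (%.3g..%.3g Hz), %d cycles\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              object@nCycles))
  cat(sprintf("  gain peak %.3f at %.3g Hz; coherence %s\n",
              max(object@gain), object@freqs[which.max(object@gain)],
              if (all(is.na(object@coherence))) "not computed"
              else sprintf("median %.3f", stats::median(object@coherence))))
  if (length(object@ci)) cat("  bootstrap bounds:",
                             paste(names(object@ci), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CalibrationModel
## ---------------------------------------------------------------------------

#' COP-regression calibration model
#'
#' Linear map from hip and shoulder marker translations to centre-of-mass
#' translation, fitted on a quasi-static trial where the centre of pressure
#' equals the COM's vertical ground projection.
#'
#' @slot coefHip,coefShoulder dimensionless regression coefficients.
#' @slot intercept metres.
#' @slot comHeight COM height above the ankle axis, metres.
#' @slot rSquared coefficient of determination of the calibration fit.
#' @export
setClass("CalibrationModel",
  representation(coefHip = "numeric", coefShoulder = "numeric",
                 intercept = "numeric", comHeight = "numeric",
                 rSquared = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@comHeight <= 0) return("comHeight must be positive")
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: com_x = %.4g + %.4f hip_x + %.4f shoulder_x  (R^2 = %.5f)\n",
    object@intercept, object@coefHip, object@coefShoulder, object@rSquared))
  cat(sprintf("  COM height %.3f m\n", object@comHeight))
})

## ---------------------------------------------------------------------------
## TrendFit
## ---------------------------------------------------------------------------

#' Hierarchical trend model fit
#'
#' Posterior summaries of the random-slope model
#' `y_ij = (beta0 + b0_i) + (beta1 + b1_i) seq_j + eps_ij` with correlated
#' subject effects, fitted by MCMC.
#'
#' @slot summary data.frame of posterior mean, sd, 2.5/97.5% quantiles and
#'   split-Rhat per parameter.
#' @slot draws matrix of pooled posterior draws (one column per parameter).
#' @slot response name of the modelled variable.
#' @slot nChains,nIter,nWarmup sampler settings (iterations include warmup).
#' @slot seed integer seed the chains were initialised from.
#' @export
setClass("TrendFit",
  representation(summary = "data.frame", draws = "matrix",
                 response = "character", nChains = "integer",
                 nIter = "integer", nWarmup = "integer", seed = "integer"))

setValidity("TrendFit", function(object) {
  need <- c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b0b1", "sigma")
  if (!all(need %in% object@summary$parameter))
    return("summary must contain the six model parameters")
  s <- object@summary
  if (any(s$q2.5 > s$q97.5)) return("credible bounds must be ordered")
  rho <- s[s$parameter == "corr_b0b1", ]
  if (rho$mean < -1 || rho$mean > 1) return("corr_b0b1 must lie in [-1, 1]")
  TRUE
})

#' Posterior summary table of a trend fit
#' @param object a [TrendFit-class].
#' @return data.frame of posterior summaries.
#' @export
setGeneric("trendSummary", function(object) standardGeneric("trendSummary"))

#' @rdname trendSummary
#' @export
setMethod("trendSummary", "TrendFit", function(object) object@summary)

#' Pooled posterior draws of a trend fit
#' @param object a [TrendFit-class].
#' @return matrix of draws, one column per parameter.
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "TrendFit", function(object) object@draws)

#' Is the population slope credibly different from zero?
#'
#' `TRUE` when the central 95% credible interval of the population slope
#' excludes zero.
#'
#' @param object a [TrendFit-class].
#' @return logical.
#' @export
setGeneric("slopeSignificant", function(object) standardGeneric("slopeSignificant"))

#' @rdname slopeSignificant
#' @export
setMethod("slopeSignificant", "TrendFit", function(object) {
  s <- object@summary
  b1 <- s[s$parameter == "beta1", ]
  b1$q2.5 > 0 || b1$q97.5 < 0
})

setMethod("show", "TrendFit", function(object) {
  s <- object@summary
  b1 <- s[s$parameter == "beta1", ]
  cat(sprintf("TrendFit for '%s' (%d chains x %d iter, %d warmup)\n",
              object@response, object@nChains, object@nIter, object@nWarmup))
  cat(sprintf("  slope %.4g [%.4g, %.4g]%s; max Rhat %.3f\n",
              b1$mean, b1$q2.5, b1$q97.5,
              if (slopeSignificant(object)) " *" else "",
              max(s$rhat, na.rm = TRUE)))
})
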