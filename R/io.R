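## Reading and writing the package's plain-text formats.  Column names carry
## units so mismatches fail loudly.

#' @importFrom utils read.csv write.csv
#' @importFrom jsonlite read_json write_json
NULL

RECORDING_COLS <- c("time_s", "platform_tilt_deg", "hip_x_m", "shoulder_x_m",
                    "cop_x_m")

## error when a channel contains a run of missing values longer than 1 s
checkNaRuns <- function(df, sampleRate) {
  for (nm in setdiff(names(df), "time_s")) {
    r <- rle(is.na(df[[nm]]))
    bad <- r$lengths[r$values] / sampleRate
    if (any(bad > 1))
      stop(sprintf("column '%s' has a %.2f s run of missing samples",
                   nm, max(bad)), call. = FALSE)
  }
}

#' Write / read a sway recording
#'
#' Recordings are stored as CSV (`time_s, platform_tilt_deg, hip_x_m,
#' shoulder_x_m, cop_x_m[, com_deg_truth]`) with a JSON sidecar
#' (`<path>.json`) carrying subject, trial label and sampling rate.
#'
#' @param rec a [SwayRecording-class].
#' @param path CSV file path.
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns a [SwayRecording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "SwayRecording"))
  n <- recordingLength(rec)
  df <- data.frame(time_s = (0:(n - 1)) / sampleRate(rec),
                   platform_tilt_deg = platformTilt(rec),
                   hip_x_m = hipX(rec), shoulder_x_m = shoulderX(rec),
                   cop_x_m = copX(rec))
  if (!all(is.na(comAngle(rec)))) df$com_deg_truth <- comAngle(rec)
  write.csv(df, path, row.names = FALSE)
  write_json(list(subject_id = subjectId(rec), trial_label = trialLabel(rec),
                  sample_rate_hz = sampleRate(rec)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(RECORDING_COLS, names(df))
  if (length(missing))
    stop(sprintf("recording file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) read_json(side, simplifyVector = TRUE)
          else list()
  sr <- meta$sample_rate_hz
  if (is.null(sr)) sr <- 1 / stats::median(diff(df$time_s))
  checkNaRuns(df, sr)
  new("SwayRecording",
      platformTilt = df$platform_tilt_deg,
      comAngle = if ("com_deg_truth" %in% names(df)) df$com_deg_truth
                 else rep(NA_real_, nrow(df)),
      hipX = df$hip_x_m, shoulderX = df$shoulder_x_m, copX = df$cop_x_m,
      sampleRate = sr,
      subjectId = if (is.null(meta$subject_id)) "unknown" else meta$subject_id,
      trialLabel = if (is.null(meta$trial_label)) "unknown"
                   else meta$trial_label)
}

#' Write / read a stimulus sequence
#'
#' Stimuli are stored as CSV (`time_s, tilt_deg, tilt_velocity_deg_s`) with
#' a JSON sidecar carrying label, cycle structure, excited frequencies and
#' the generator configuration.  If the velocity column is absent on read,
#' it is reconstructed from forward differences of the tilt trace (the exact
#' midpoint velocity for piecewise-linear stimuli).
#'
#' @param stim a [StimulusSequence-class].
#' @param path CSV file path.
#' @return `writeStimulus` returns `path` invisibly; `readStimulus` returns
#'   a [StimulusSequence-class].
#' @export
writeStimulus <- function(stim, path) {
  stopifnot(is(stim, "StimulusSequence"))
  n <- length(tiltAngle(stim))
  df <- data.frame(time_s = (0:(n - 1)) / sampleRate(stim),
                   tilt_deg = tiltAngle(stim),
                   tilt_velocity_deg_s = tiltVelocity(stim))
  write.csv(df, path, row.names = FALSE)
  write_json(list(label = stimulusLabel(stim),
                  sample_rate_hz = sampleRate(stim),
                  cycle_duration_s = cycleDuration(stim),
                  n_cycles = nCycles(stim),
                  excited_frequencies_hz = excitedFrequencies(stim),
                  velocity_magnitude_deg_s = stim@velocityMagnitude,
                  config = stim@config),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStimulus
#' @export
readStimulus <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "tilt_deg") %in% names(df)))
    stop("stimulus file must have columns time_s and tilt_deg", call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop(sprintf("stimulus sidecar '%s' not found", side), call. = FALSE)
  meta <- read_json(side, simplifyVector = TRUE)
  sr <- meta$sample_rate_hz
  checkNaRuns(df, sr)
  vel <- if ("tilt_velocity_deg_s" %in% names(df)) df$tilt_velocity_deg_s
         else { d <- diff(df$tilt_deg) * sr; c(d, d[length(d)]) }
  cfg <- if (is.null(meta$config)) list() else as.list(meta$config)
  new("StimulusSequence",
      samples = df$tilt_deg, velocity = vel, sampleRate = sr,
      cycleDuration = meta$cycle_duration_s,
      nCycles = as.integer(meta$n_cycles),
      excitedFrequencies = as.numeric(meta$excited_frequencies_hz),
      label = meta$label,
      velocityMagnitude =
        if (is.null(meta$velocity_magnitude_deg_s)) NA_real_
        else as.numeric(meta$velocity_magnitude_deg_s),
      config = cfg)
}
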