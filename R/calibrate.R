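## Quasi-static COP-regression calibration: convert hip/shoulder marker
## translations into angular COM sway.

#' Fit the COP-regression calibration
#'
#' In quasi-static stance the centre of pressure equals the vertical ground
#' projection of the centre of mass, so an ordinary least-squares regression
#' of `cop_x` on the hip and shoulder translations of a slow ankle-and-hip
#' movement trial yields the coefficients that map marker translations to
#' COM translation during dynamic trials.
#'
#' @param rec a [SwayRecording-class] of the calibration trial (>= 30 s,
#'   with hip, shoulder and COP channels).
#' @param comHeight COM height above the ankle axis, m (from anthropometric
#'   tables).
#' @return a [CalibrationModel-class].
#' @examples
#' p <- balanceModelParams(copNoiseSd = 0)
#' cal <- fitCalibration(simulateCalibrationTrial(p), p$comHeight)
#' cal
#' @export
fitCalibration <- function(rec, comHeight) {
  stopifnot(is(rec, "SwayRecording"))
  stopIfNot1(comHeight, "comHeight")
  if (comHeight <= 0) stop("comHeight must be positive")
  n <- recordingLength(rec)
  if (n / sampleRate(rec) < 30)
    stop("calibration recording must be at least 30 s long")
  hip <- hipX(rec); shoulder <- shoulderX(rec)
  X <- cbind(1, hip, shoulder)
  if (qr(X)$rank < 3L)
    stop(paste0("hip and shoulder translations are collinear; the ",
                "calibration movement needs independent hip motion"),
         call. = FALSE)
  fit <- stats::lm.fit(X, copX(rec))
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((copX(rec) - mean(copX(rec)))^2)
  new("CalibrationModel",
      coefHip = unname(fit$coefficients[2L]),
      coefShoulder = unname(fit$coefficients[3L]),
      intercept = unname(fit$coefficients[1L]),
      comHeight = comHeight, rSquared = max(0, min(1, r2)))
}

#' Apply a calibration model
#'
#' Maps a recording's marker translations to COM translation,
#' `com_x = intercept + coefHip hip_x + coefShoulder shoulder_x`, and
#' converts to angular COM sway `asin(com_x / comHeight)` in degrees.  The
#' inverse-sine map (rather than the small-angle ratio) keeps the conversion
#' exact; the difference is negligible below 5 degrees but the convention is
#' fixed.
#'
#' @param model a [CalibrationModel-class].
#' @param rec a [SwayRecording-class].
#' @return numeric COM angle trace, degrees.
#' @export
applyCalibration <- function(model, rec) {
  stopifnot(is(model, "CalibrationModel"), is(rec, "SwayRecording"))
  comX <- model@intercept + model@coefHip * hipX(rec) +
    model@coefShoulder * shoulderX(rec)
  if (any(abs(comX) > model@comHeight))
    stop(paste0("non-physical calibration output: |COM translation| ",
                "exceeds the COM height"), call. = FALSE)
  rad2deg(asin(comX / model@comHeight))
}
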