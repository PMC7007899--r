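## internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Derive reproducible child seeds from a master seed
#'
#' Stage-level randomness (stimulus order, per-subject parameters, trial
#' noise, bootstrap resampling, MCMC chains) is driven by child seeds drawn
#' from the master seed, so that stages can be re-run independently and the
#' whole pipeline is reproducible from a single integer.
#'
#' @param master single integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

## phase unwrapping in degrees: remove 360-degree jumps along a vector
unwrapDeg <- function(phase) {
  if (length(phase) < 2L) return(phase)
  d <- diff(phase)
  jumps <- round(d / 360)
  phase - c(0, cumsum(jumps)) * 360
}

## wrap a phase difference into (-180, 180]
wrapDeg <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

## low-pass filtered Gaussian torque noise with stationary sd `sd` and
## first-order time constant `tau` (s); returns n samples at rate sr
filteredNoise <- function(n, sd, tau, sr) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / (tau * sr))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  stats::filter(innov, a, method = "recursive", init = stats::rnorm(1, 0, sd))
}

stopIfNot1 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  invisible(x)
}
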