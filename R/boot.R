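## Cycle-resampling bootstrap confidence bounds for time-domain means, FRFs
## and coherence.

#' Bootstrap configuration
#'
#' @param nBoot number of bootstrap samples (default 400).
#' @param ciLevel two-sided confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return configuration list (class `"BootstrapConfig"`).
#' @export
bootstrapConfig <- function(nBoot = 400L, ciLevel = 0.95, seed = 1L) {
  nBoot <- as.integer(nBoot)
  if (nBoot < 40L) stop("nBoot must be >= 40")
  if (ciLevel <= 0 || ciLevel >= 1) stop("ciLevel must lie in (0, 1)")
  structure(list(nBoot = nBoot, ciLevel = ciLevel, seed = as.integer(seed)),
            class = "BootstrapConfig")
}

#' Order-statistic indices of the bootstrap confidence bounds
#'
#' With the replicates sorted in ascending order, the lower and upper bounds
#' are the order statistics at `round(nBoot (1 - ciLevel) / 2)` and
#' `round(nBoot (1 + ciLevel) / 2)`: for 400 samples at the 95% level these
#' are the 10th and 390th values (the 2.5% and 97.5% points).
#'
#' @param nBoot number of bootstrap samples.
#' @param ciLevel two-sided confidence level.
#' @return integer vector `c(low, high)`, 1-based.
#' @examples
#' ciIndices(400, 0.95)    # 10 390
#' @export
ciIndices <- function(nBoot, ciLevel = 0.95) {
  if (nBoot * (1 - ciLevel) / 2 < 1)
    stop(sprintf("too few replicates: %d samples cannot resolve the %g%% level",
                 nBoot, 100 * ciLevel), call. = FALSE)
  c(low = round(nBoot * (1 - ciLevel) / 2),
    high = round(nBoot * (1 + ciLevel) / 2))
}

#' Bootstrap a cycle statistic
#'
#' Draws `nBoot` resamples of the cycle pool (rows drawn with replacement,
#' resample size equal to the pool size), recomputes the statistic on each
#' resample, sorts each scalar output element across replicates and applies
#' the order-statistic index rule of [ciIndices()].  Deterministic given the
#' config seed.
#'
#' @param x the cycle pool: a [CycleSet-class] (rows are cycles) or a
#'   numeric matrix (rows are the resampling unit).
#' @param statistic function mapping an object like `x` to a numeric vector
#'   (mean trace, FRF gains, coherence, a scalar mean, ...).
#' @param config a [bootstrapConfig()] list.
#' @param replicates also return the full replicate matrix.
#' @return list with `estimate` (statistic on the original pool), `lower`,
#'   `upper` (element-wise bounds) and optionally `replicates`
#'   (`nBoot` x `length(estimate)`).
#' @export
bootstrapStatistic <- function(x, statistic, config = bootstrapConfig(),
                               replicates = FALSE) {
  stopifnot(inherits(config, "BootstrapConfig"), is.function(statistic))
  n <- if (is(x, "CycleSet")) nCycles(x) else nrow(x)
  if (is.null(n) || n < 1L) stop("empty cycle pool", call. = FALSE)
  est <- statistic(x)
  idx <- ciIndices(config$nBoot, config$ciLevel)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  reps <- matrix(NA_real_, config$nBoot, length(est))
  for (b in seq_len(config$nBoot)) {
    take <- sample.int(n, n, replace = TRUE)
    reps[b, ] <- statistic(x[take, , drop = FALSE])
  }
  sorted <- apply(reps, 2L, sort)
  out <- list(estimate = est, lower = sorted[idx[1L], ],
              upper = sorted[idx[2L], ])
  if (replicates) out$replicates <- reps
  out
}

#' Attach bootstrap bounds to a frequency response
#'
#' Bootstraps gain, phase and coherence over the cycle pool and stores the
#' element-wise bounds in the `ci` slot of the returned
#' [FrequencyResponse-class].
#'
#' @param cs a [CycleSet-class].
#' @param excited excited frequencies, Hz.
#' @param config a [bootstrapConfig()] list.
#' @return a [FrequencyResponse-class] with `ci` filled for `gain`, `phase`
#'   and `coherence`.
#' @export
frfWithBootstrap <- function(cs, excited, config = bootstrapConfig()) {
  fr <- estimateFRF(cs, excited, withCoherence = TRUE)
  p <- length(fr@freqs)
  ## the per-cycle DFT is row-wise, so resampling cycles and re-running the
  ## estimators is identical to resampling rows of the precomputed spectra;
  ## the spectra are computed once and only the averaging is repeated
  bins <- harmonicBins(fr@freqs, cycleDuration(cs))
  S <- cycleSpectra(stimulusCycles(cs), bins)
  R <- cycleSpectra(responseCycles(cs), bins)
  ratio <- R / S
  cross <- Conj(S) * R
  pS <- Mod(S)^2
  pR <- Mod(R)^2
  n <- nrow(S)
  stat <- function(idx) {
    frf <- colMeans(ratio[idx, , drop = FALSE])
    coh <- pmin(1, Mod(colMeans(cross[idx, , drop = FALSE]))^2 /
                  (colMeans(pS[idx, , drop = FALSE]) *
                   colMeans(pR[idx, , drop = FALSE])))
    c(Mod(frf), unwrapDeg(wrapDeg(rad2deg(Arg(frf)))), coh)
  }
  bs <- bootstrapStatistic(matrix(seq_len(n), ncol = 1L),
                           function(m) stat(m[, 1L]), config)
  pick <- function(off) cbind(lower = bs$lower[off + seq_len(p)],
                              upper = bs$upper[off + seq_len(p)])
  fr@ci <- list(gain = pick(0L), phase = pick(p), coherence = pick(2L * p))
  validObject(fr)
  fr
}
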