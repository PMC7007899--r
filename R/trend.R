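## Hierarchical linear trend model across learning trials: population slope,
## correlated subject-level intercepts/slopes, 95% credible intervals.

trendModelString <- "
model {
  for (n in 1:N) {
    y[n] ~ dnorm(b[subj[n], 1] + b[subj[n], 2] * x[n], tau)
  }
  for (i in 1:S) {
    b[i, 1:2] ~ dmnorm(mu[], Omega[,])
  }
  mu[1] ~ dnorm(0, betaPrec)
  mu[2] ~ dnorm(0, betaPrec)
  sd0 ~ dt(0, sdPrec, 1) T(0,)
  sd1 ~ dt(0, sdPrec, 1) T(0,)
  rho ~ dunif(-1, 1)
  Sig[1, 1] <- sd0 * sd0 + 1.0E-10
  Sig[2, 2] <- sd1 * sd1 + 1.0E-10
  Sig[1, 2] <- rho * sd0 * sd1
  Sig[2, 1] <- Sig[1, 2]
  Omega[1:2, 1:2] <- inverse(Sig[,])
  sigma ~ dt(0, sigmaPrec, 1) T(0,)
  tau <- pow(sigma, -2)
}
"

## split-Rhat: split each chain in half and apply the potential scale
## reduction factor to the half-chains
splitRhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    m <- floor(nrow(ch) / 2)
    halves <- c(halves, list(ch[seq_len(m), , drop = FALSE],
                             ch[m + seq_len(m), , drop = FALSE]))
  }
  ml <- coda::mcmc.list(lapply(halves, coda::mcmc))
  coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1L]
}

#' Fit the hierarchical trend model
#'
#' Fits `y_ij = (beta0 + b0_i) + (beta1 + b1_i) seq_j + eps_ij` with
#' correlated subject-level intercepts and slopes by MCMC (JAGS):
#' `dependent ~ seq + (seq | subject)`.  Priors are weakly informative:
#' Normal(0, 10) on the population intercept and slope, Half-Cauchy(0, 2) on
#' the group-level standard deviations and the residual standard deviation,
#' and uniform on the intercept-slope correlation.  Trial indices must be
#' coded from 0 so the intercept refers to the first trial.  Convergence is
#' diagnosed with split-Rhat; values above 1.05 trigger a warning.
#'
#' @param data data.frame with the trial series.
#' @param response name of the dependent column.
#' @param subject,index names of the subject and 0-based trial-index
#'   columns.
#' @param nChains number of chains.
#' @param nIter iterations per chain, including warmup.
#' @param nWarmup warmup (adaptation + burn-in) iterations per chain.
#' @param priors list with `betaSd`, `sdScale`, `sigmaScale`.
#' @param seed integer seed; chain RNGs derive from it.
#' @return a [TrendFit-class].
#' @examples
#' \donttest{
#' d <- expand.grid(subject = sprintf("S%02d", 1:6), trial = 0:19)
#' d$y <- 2 - 0.01 * d$trial + rnorm(nrow(d), 0, 0.05)
#' fit <- fitTrend(d, "y", nChains = 2, nIter = 1000, nWarmup = 500, seed = 1)
#' trendSummary(fit)
#' }
#' @export
fitTrend <- function(data, response, subject = "subject", index = "trial",
                     nChains = 4L, nIter = 4000L, nWarmup = 2000L,
                     priors = list(betaSd = 10, sdScale = 2, sigmaScale = 2),
                     seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c(response, subject, index) %in% names(data)))
  y <- data[[response]]
  x <- data[[index]]
  if (min(x, na.rm = TRUE) != 0)
    stop("trial indices must be coded starting at 0", call. = FALSE)
  subj <- as.integer(factor(data[[subject]]))
  S <- max(subj)
  if (S < 2L)
    stop(paste0("a single subject cannot identify the group level; ",
                "use a simple linear regression instead"), call. = FALSE)
  nIter <- as.integer(nIter); nWarmup <- as.integer(nWarmup)
  nChains <- as.integer(nChains)
  if (nWarmup >= nIter) stop("nWarmup must be smaller than nIter")

  jdata <- list(y = y, x = x, subj = subj, N = length(y), S = S,
                betaPrec = priors$betaSd^-2, sdPrec = priors$sdScale^-2,
                sigmaPrec = priors$sigmaScale^-2)
  chainSeeds <- deriveSeeds(seed, nChains)
  ## start every chain at the per-subject OLS solution; the group-level
  ## posterior is a funnel when residual noise is small and default inits
  ## strand the sampler far from the mode
  ols <- t(vapply(seq_len(S), function(i) {
    sel <- subj == i
    stats::lm.fit(cbind(1, x[sel]), y[sel])$coefficients
  }, numeric(2)))
  resid <- y - ols[subj, 1L] - ols[subj, 2L] * x
  init0 <- list(mu = colMeans(ols),
                b = ols,
                sd0 = max(stats::sd(ols[, 1L]), 1e-3),
                sd1 = max(stats::sd(ols[, 2L]), 1e-4),
                rho = 0,
                sigma = max(stats::sd(resid), 1e-4))
  inits <- lapply(chainSeeds, function(s)
    c(init0, list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)))

  nAdapt <- min(500L, max(100L, nWarmup %/% 2L))
  jm <- rjags::jags.model(textConnection(trendModelString), data = jdata,
                          n.chains = nChains, n.adapt = nAdapt,
                          inits = inits, quiet = TRUE)
  extraBurn <- nWarmup - nAdapt
  if (extraBurn > 0) stats::update(jm, n.iter = extraBurn, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, c("mu", "sd0", "sd1", "rho", "sigma"),
    n.iter = nIter - nWarmup, progress.bar = "none")

  rename <- c(`mu[1]` = "beta0", `mu[2]` = "beta1", sd0 = "sd_b0",
              sd1 = "sd_b1", rho = "corr_b0b1", sigma = "sigma")
  chains <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    colnames(m) <- rename[colnames(m)]
    m[, c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b0b1", "sigma"),
      drop = FALSE]
  })
  draws <- do.call(rbind, chains)
  rhat <- if (nChains >= 2L) splitRhat(chains)
          else rep(NA_real_, ncol(draws))

  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  summary <- data.frame(parameter = colnames(draws),
                        mean = colMeans(draws),
                        sd = apply(draws, 2L, stats::sd),
                        q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                        rhat = as.numeric(rhat), row.names = NULL)
  if (any(summary$rhat > 1.05, na.rm = TRUE))
    warning(sprintf("possible non-convergence: max split-Rhat %.3f",
                    max(summary$rhat, na.rm = TRUE)), call. = FALSE)

  new("TrendFit", summary = summary, draws = draws, response = response,
      nChains = nChains, nIter = nIter, nWarmup = nWarmup,
      seed = as.integer(seed))
}
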