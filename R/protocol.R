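## Session orchestration: the end-to-end synthetic reproduction pipeline
## (simulate cohort -> calibrate -> analyse -> bootstrap -> trend).

#' Session configuration
#'
#' Bundles every setting of the synthetic protocol: stimulus construction,
#' simulator and cohort parameters, analysis settings and the master seed.
#' A run is reproducible from `(config, seed)` alone.  The protocol mirrors
#' the experimental ordering: warm-up and three pseudo-random test sequences
#' (pre), 75 learning trials, then the pseudo-random sequences again (post).
#' The post-phase controller carries the end-of-learning parameter values,
#' so the pre/post contrast has a configured effect size.
#'
#' @param seed master seed; every stage seed derives from it.
#' @param stages subset of `c("pre", "learning", "post")` to execute.
#' @param nSubjects,nTrials cohort size and learning-trial count.
#' @param prtsCycles cycles per pseudo-random test sequence.
#' @param sampleRate sampling rate, Hz.
#' @param params baseline [balanceModelParams()].
#' @param cohort a [learningCohortConfig()]; its seed/params/size fields are
#'   overridden by this config's.
#' @param discardFirst discard the first cycle of each pseudo-random trial.
#' @param nBoot,ciLevel bootstrap settings for the FRF bounds.
#' @param trendMetrics metric columns to fit trend models for.
#' @param trendChains,trendIter,trendWarmup MCMC settings.
#' @return configuration list (class `"SessionConfig"`).
#' @export
sessionConfig <- function(seed = 1L, stages = c("pre", "learning", "post"),
                          nSubjects = 19L, nTrials = 75L, prtsCycles = 18L,
                          sampleRate = 100,
                          params = balanceModelParams(),
                          cohort = learningCohortConfig(),
                          discardFirst = TRUE, nBoot = 400L, ciLevel = 0.95,
                          trendMetrics = c("stim_psd", "starting_position",
                                           "low_psd"),
                          trendChains = 2L, trendIter = 1500L,
                          trendWarmup = 750L) {
  stages <- match.arg(stages, c("pre", "learning", "post"),
                      several.ok = TRUE)
  structure(list(seed = as.integer(seed), stages = stages,
                 nSubjects = as.integer(nSubjects),
                 nTrials = as.integer(nTrials),
                 prtsCycles = as.integer(prtsCycles),
                 sampleRate = sampleRate, params = params, cohort = cohort,
                 discardFirst = discardFirst, nBoot = as.integer(nBoot),
                 ciLevel = ciLevel, trendMetrics = trendMetrics,
                 trendChains = as.integer(trendChains),
                 trendIter = as.integer(trendIter),
                 trendWarmup = as.integer(trendWarmup)),
            class = "SessionConfig")
}

## internal: per-subject parameter draws for one pseudo-random phase
phaseSubjectParams <- function(cfg, lean, w, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  sd <- cfg$cohort$subjectSd
  out <- lapply(seq_len(cfg$nSubjects), function(i) {
    p <- cfg$params
    p$leanSetpoint <- lean + stats::rnorm(1, 0, sd$lean)
    p$wProp <- min(max(w + stats::rnorm(1, 0, sd$w), 0.05), 0.95)
    p$Kp <- p$Kp * exp(stats::rnorm(1, 0, sd$logKp))
    p
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

## internal: simulate one pseudo-random phase and estimate FRFs with bounds
runPrtsPhase <- function(cfg, stimuli, subjParams, calModels, seedBase,
                         phase) {
  frfs <- list()
  pools <- list()
  for (s in seq_along(stimuli)) {
    stim <- stimuli[[s]]
    sets <- vector("list", cfg$nSubjects)
    for (i in seq_len(cfg$nSubjects)) {
      rec <- simulateSway(stim, subjParams[[i]],
                          seed = (seedBase + 1000 * s + i) %% 2147483640 + 1,
                          subjectId = sprintf("S%02d", i),
                          trialLabel = paste0(phase, "_", names(stimuli)[s]))
      com <- applyCalibration(calModels[[i]], rec)
      sets[[i]] <- segmentCycles(rec, cycleDuration(stim),
                                 discardFirst = cfg$discardFirst,
                                 response = com)
    }
    pool <- combineCycleSets(sets)
    pools[[names(stimuli)[s]]] <- pool
    frfs[[names(stimuli)[s]]] <- frfWithBootstrap(
      pool, excitedFrequencies(stim),
      bootstrapConfig(cfg$nBoot, cfg$ciLevel,
                      seed = (seedBase + s) %% 2147483640 + 1))
  }
  list(frf = frfs, pools = pools)
}

#' Run the full synthetic protocol
#'
#' Executes the configured stages on a simulated cohort: subject-wise
#' calibration, the pre pseudo-random phase (three amplitudes, FRF +
#' coherence with bootstrap bounds over the pooled cycle set), the learning
#' phase (per-trial metrics and hierarchical trend fits), and the post
#' pseudo-random phase with the end-of-learning parameter values.  When
#' `outDir` is given, results tables and a manifest (seeds, settings, file
#' checksums) are written; rerunning with the same config yields an
#' identical manifest.
#'
#' @param cfg a [sessionConfig()] list.
#' @param outDir optional output directory.
#' @return list with elements `stimuli`, `calibrations`, `pre`, `post`
#'   (FRF lists), `metrics`, `trends`, `truth` and `manifest`.
#' @export
runProtocol <- function(cfg = sessionConfig(), outDir = NULL) {
  stopifnot(inherits(cfg, "SessionConfig"))
  seeds <- deriveSeeds(cfg$seed, 8L)
  res <- list()

  session <- assembleSession(nCycles = cfg$prtsCycles,
                             sampleRate = cfg$sampleRate, seed = seeds[1L])
  learnStim <- buildLearningSequence(sampleRate = cfg$sampleRate)
  res$stimuli <- c(session, list(learning = learnStim))

  ## per-subject calibration (one quasi-static trial each)
  calParams <- cfg$params
  if (calParams$hipAmp == 0) calParams$hipAmp <- 0.5  # calibration realism
  calModels <- lapply(seq_len(cfg$nSubjects), function(i)
    fitCalibration(simulateCalibrationTrial(calParams,
                                            seed = (seeds[2L] + i) %% 2147483640 + 1,
                                            subjectId = sprintf("S%02d", i)),
                   cfg$params$comHeight))
  res$calibrations <- calModels

  co <- cfg$cohort
  if ("pre" %in% cfg$stages) {
    pre <- runPrtsPhase(cfg, session$test,
                        phaseSubjectParams(cfg, co$leanStart, co$wStart,
                                           seeds[3L]),
                        calModels, seeds[4L], "pre")
    res$pre <- pre$frf
  }

  if ("learning" %in% cfg$stages) {
    cohortCfg <- learningCohortConfig(
      nSubjects = cfg$nSubjects, nTrials = cfg$nTrials,
      leanStart = co$leanStart, leanEnd = co$leanEnd, leanTau = co$leanTau,
      wStart = co$wStart, wEnd = co$wEnd, wTau = co$wTau, drift = co$drift,
      subjectSd = co$subjectSd, params = cfg$params, seed = seeds[5L])
    recs <- simulateLearningCohort(cohortCfg, learnStim)
    res$truth <- attr(recs, "truth")
    res$metrics <- learningMetricsTable(recs, learnStim)
    res$trends <- lapply(cfg$trendMetrics, function(m)
      fitTrend(res$metrics, m, subject = "subject", index = "trial",
               nChains = cfg$trendChains, nIter = cfg$trendIter,
               nWarmup = cfg$trendWarmup, seed = seeds[6L]))
    names(res$trends) <- cfg$trendMetrics
  }

  if ("post" %in% cfg$stages) {
    post <- runPrtsPhase(cfg, session$test,
                         phaseSubjectParams(cfg, co$leanEnd, co$wEnd,
                                            seeds[3L]),
                         calModels, seeds[7L], "post")
    res$post <- post$frf
  }

  res$manifest <- list(package = "posturolab",
                       version = as.character(utils::packageVersion("posturolab")),
                       seed = cfg$seed, stageSeeds = seeds,
                       stages = cfg$stages, nSubjects = cfg$nSubjects,
                       nTrials = cfg$nTrials, prtsCycles = cfg$prtsCycles,
                       amplitudeOrder = session$order)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wr <- function(df, name) {
      p <- file.path(outDir, name)
      utils::write.csv(df, p, row.names = FALSE)
      files <<- c(files, p)
    }
    if (!is.null(res$metrics)) wr(res$metrics, "learning_metrics.csv")
    for (ph in intersect(c("pre", "post"), names(res)))
      for (nm in names(res[[ph]]))
        wr(as.data.frame(res[[ph]][[nm]]), sprintf("frf_%s_%s.csv", ph, nm))
    for (nm in names(res$trends))
      wr(trendSummary(res$trends[[nm]]), sprintf("trend_%s.csv", nm))
    md5 <- tools::md5sum(files)
    res$manifest$files <- data.frame(file = basename(files),
                                     md5 = unname(md5))
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
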