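## shared fixtures, built in code

## deterministic noise-free model for oracle comparisons
quietParams <- function(...) {
  args <- list(...)
  if (is.null(args$noiseSd)) args$noiseSd <- 0
  if (is.null(args$copNoiseSd)) args$copNoiseSd <- 0
  do.call(balanceModelParams, args)
}

## a synthetic recording whose channels are arbitrary periodic traces; cheap
## stand-in when the dynamics do not matter (segmentation, IO, bootstrap
## bookkeeping)
fakeRecording <- function(stimCycle, respCycle, nCycles, sampleRate = 100,
                          subject = "S01", trial = "pp4") {
  stim <- rep(stimCycle, nCycles)
  resp <- rep(respCycle, nCycles)
  n <- length(stim)
  new("SwayRecording", platformTilt = stim, comAngle = resp,
      hipX = numeric(n), shoulderX = numeric(n), copX = numeric(n),
      sampleRate = sampleRate, subjectId = subject, trialLabel = trial)
}

## one 20-s PRTS cycle at a reduced rate for cheap bookkeeping tests
prtsCycleLowRate <- function(sampleRate = 20) {
  tiltAngle(buildPRTS(ternaryDesign(), 1.78, nCycles = 1,
                      sampleRate = sampleRate))
}
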