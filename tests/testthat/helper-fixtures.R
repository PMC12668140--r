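# Shared fixtures, built in code at test time.

# Small synthetic cohort for staging tests (cached per session).
smallCohort <- local({
  cache <- NULL
  function(n = 3, durationS = 1800, seedBase = 100) {
    key <- paste(n, durationS, seedBase)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    subs <- lapply(seq_len(n), function(i) {
      s <- simulateSession(subject = paste0("s", i), durationS = durationS,
                           nCells = 0, seed = seedBase + i)
      extractStagingFeatures(s)
    })
    attr(subs, "key") <- key
    cache <<- subs
    subs
  }
})

# Hypnogram with a fixed run-length structure, e.g. runHypno(WAKE = 20,
# NREM = 5, WAKE = 15).
runHypno <- function(..., windowS = 2.5) {
  runs <- c(...)
  Hypnogram(rep(names(runs), runs), windowS = windowS)
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration (the
# independent oracle; sums the probabilities of all tables with the
# observed margins whose probability does not exceed the observed one).
fisherEnumP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Stylized action-potential sweep: resting vRest with spikes (3 ms
# triangular waveforms peaking at vPeak) at the given times (ms).
spikeSweep <- function(spikeTimesMs, durMs = 1000, dt = 0.05,
                      vRest = -70, vPeak = 30) {
  v <- rep(vRest, round(durMs / dt))
  up <- seq(0, 1, length.out = round(1.5 / dt) + 1)
  for (t0 in spikeTimesMs) {
    i0 <- round(t0 / dt)
    riseIdx <- i0 + seq_along(up) - 1
    v[riseIdx] <- vRest + (vPeak - vRest) * up^3
    fallIdx <- max(riseIdx) + seq_along(up)
    v[fallIdx] <- vPeak - (vPeak - vRest) * up
  }
  v
}

# Square current step protocol responses from the linear membrane.
stepSweeps <- function(params, currents, dt = 0.1, preS = 0.2, stepS = 1,
                       postS = 0.4) {
  stim <- function(a) c(rep(0, round(preS * 1000 / dt)),
                        rep(a, round(stepS * 1000 / dt)),
                        rep(0, round(postS * 1000 / dt)))
  vapply(currents, function(a) simulateMembrane(params, stim(a), dt),
         numeric(length(stim(0))))
}
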