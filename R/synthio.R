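# Synthetic multimodal session generator with known ground truth.
# Everything downstream (staging, metrics, calcium, ephys) is validated
# against the latent variables produced here.

# Evaluate expr under a fixed RNG seed without disturbing global RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Default bout-level transition matrix
#'
#' A realistic mouse sleep structure: wake bouts end in NREM, NREM bouts
#' end in wake or REM, REM bouts end mostly in wake. The diagonal is
#' structurally zero (a bout ends when the state changes) and the
#' WAKE to REM entry is zero, as direct wake-to-REM transitions are not
#' part of normal murine sleep architecture.
#'
#' @return 3x3 row-stochastic matrix with dimnames WAKE/NREM/REM.
#' @export
defaultTransitionMatrix <- function() {
  m <- matrix(c(
    0.0, 1.0, 0.0,
    0.7, 0.0, 0.3,
    0.8, 0.2, 0.0
  ), nrow = 3, byrow = TRUE,
  dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))
  m
}

#' Simulate a Markov vigilance-state sequence
#'
#' Generates a bout-level first-order Markov chain over
#' \{WAKE, NREM, REM\} and expands it onto a fixed window grid. Bout
#' dwell times are geometric (memoryless) with the given per-state means,
#' consistent with modeling state transitions as a first-order Markov
#' process.
#'
#' @param transitionMatrix 3x3 row-stochastic matrix of bout-level
#'   transition probabilities (rows = from-state, in WAKE/NREM/REM order).
#' @param dwellWindows mean bout dwell per state, in windows (length 3 or
#'   scalar).
#' @param nWindows number of windows to generate (>= 1).
#' @param windowS seconds per window.
#' @param startState initial state label.
#' @param seed integer seed; the sequence is bit-reproducible given the seed.
#' @return A [StateSequence-class] (a [Hypnogram-class] carrying the
#'   generating bout table and seed).
#' @examples
#' ss <- simulateStateSequence(nWindows = 200, seed = 1)
#' table(stateLabels(ss))
#' @export
simulateStateSequence <- function(transitionMatrix = defaultTransitionMatrix(),
                                  dwellWindows = 60, nWindows = 2880,
                                  windowS = 2.5, startState = "WAKE",
                                  seed = 1) {
  stopifnot(nWindows >= 1, windowS > 0)
  transitionMatrix <- as.matrix(transitionMatrix)
  if (!all(dim(transitionMatrix) == c(3L, 3L)) ||
      any(transitionMatrix < 0) ||
      any(abs(rowSums(transitionMatrix) - 1) > 1e-9))
    stop("transitionMatrix must be 3x3 row-stochastic (rows summing to 1)")
  dwellWindows <- rep_len(dwellWindows, 3L)
  stopifnot(all(dwellWindows >= 1))
  startState <- match.arg(startState, VIGILANCE_STATES)

  withSeed(seed, {
    states <- integer(0)
    dwells <- integer(0)
    cur <- match(startState, VIGILANCE_STATES)
    total <- 0L
    while (total < nWindows) {
      # geometric dwell with mean dwellWindows[cur], support >= 1 window
      m <- dwellWindows[cur]
      d <- if (m <= 1) 1L else rgeom(1L, prob = 1 / m) + 1L
      states <- c(states, cur)
      dwells <- c(dwells, d)
      total <- total + d
      cur <- sample.int(3L, 1L, prob = transitionMatrix[cur, ])
    }
    labels <- rep(VIGILANCE_STATES[states], dwells)[seq_len(nWindows)]
    new("StateSequence",
        labels = labels, windowS = windowS, provenance = "simulated",
        bouts = data.frame(state = VIGILANCE_STATES[states],
                           windows = dwells),
        seed = as.integer(seed))
  })
}

#' Default state-conditioned spectral profile
#'
#' Band power densities (uV^2/Hz), EMG tone (uV RMS) and accelerometer
#' tone (g RMS) per vigilance state, plus the 1/f background. Defaults
#' encode the canonical state signatures at well-separated contrast:
#' NREM delta power 10x wake, REM theta power 5x wake, wake EMG and
#' movement tone 5x sleep (atonia in both sleep states).
#'
#' @return A list with elements \code{bands} (named band edges in Hz),
#'   \code{states} (per-state power/tone values) and \code{onef}
#'   (1/f exponent and 1 Hz amplitude).
#' @export
defaultSpectralProfile <- function() {
  profile <- list(
    bands = list(delta = c(0.5, 4), theta = c(5, 9)),
    states = list(
      WAKE = list(delta = 10, theta = 8,  broadband = 3, emg = 30, accel = 0.05),
      NREM = list(delta = 100, theta = 10, broadband = 3, emg = 6, accel = 0.005),
      REM  = list(delta = 8,  theta = 40, broadband = 3, emg = 6, accel = 0.005)
    ),
    onef = list(exponent = 1, amp1Hz = 5)
  )
  validateSpectralProfile(profile)
  profile
}

validateSpectralProfile <- function(profile) {
  b <- profile$bands
  stopifnot(is.list(b), all(c("delta", "theta") %in% names(b)))
  edges <- do.call(rbind, b)
  if (any(edges[, 2] <= edges[, 1])) stop("band edges must be increasing")
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)]))
    stop("bands must be non-overlapping")
  for (s in VIGILANCE_STATES) {
    v <- unlist(profile$states[[s]])
    if (any(v < 0)) stop("all powers and tones must be >= 0")
  }
  invisible(TRUE)
}

# Band-limited Gaussian noise with unit one-sided PSD inside [f1,f2],
# generated by FFT masking of white noise. When the band sits far below
# the Nyquist rate the noise is synthesized at a reduced rate and
# linearly interpolated up: the interpolation rolloff at f2 is
# sinc-squared of f2/fsLow, negligible when fsLow >= 8*f2.
bandNoiseUnitPSD <- function(n, fs, f1, f2) {
  q <- max(1L, floor(fs / max(8 * f2, 25)))
  if (q > 1) {
    nLow <- ceiling(n / q) + 2L
    fsLow <- fs / q
    yLow <- bandNoiseUnitPSD(nLow, fsLow, f1, f2)
    tLow <- (seq_len(nLow) - 1) / fsLow
    return(approx(tLow, yLow, xout = (seq_len(n) - 1) / fs)$y)
  }
  m <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length composite
  x <- rnorm(m)
  X <- fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  X[f < f1 | f > f2] <- 0
  y <- Re(fft(X, inverse = TRUE)) / m
  # white N(0,1) has one-sided PSD 2/fs; rescale masked noise to PSD 1
  y[seq_len(n)] * sqrt(fs / 2)
}

# 1/f^a shaped noise with one-sided PSD amp1Hz/f^a (flat below 0.5 Hz).
onefNoise <- function(n, fs, exponent, amp1Hz) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  X <- fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  shape <- rep(1, m)
  hi <- f >= 0.5
  shape[hi] <- f[hi]^(-exponent / 2)
  shape[!hi] <- 0.5^(-exponent / 2)
  shape[1] <- 0
  y <- Re(fft(X * shape, inverse = TRUE)) / m
  y[seq_len(n)] * sqrt(amp1Hz * fs / 2)
}

#' Synthesize state-conditioned EEG, EMG and accelerometer signals
#'
#' EEG channels are built as 1/f-shaped background noise plus
#' band-limited noise whose per-sample power follows the state sequence
#' (delta and theta bands and a broadband floor). EMG and accelerometer
#' channels are white noise at the per-state tone. EMG is produced as a
#' differential pair around a shared common-mode artifact (slow drift
#' plus 50 Hz line) so that differential referencing is meaningful;
#' EEG channels share their state-conditioned power so that mean
#' re-referencing preserves the spectral contrast.
#'
#' @param states a [Hypnogram-class]/[StateSequence-class] defining the
#'   per-window state.
#' @param profile spectral profile as from [defaultSpectralProfile()].
#' @param fs sampling rate in Hz (>= 250).
#' @param nEEG number of EEG channels (>= 2, for mean re-referencing).
#' @param seed integer seed.
#' @return list with [TimeSeries-class] elements \code{eeg} (nEEG
#'   channels, uV), \code{emg} (2 channels, uV) and \code{accel}
#'   (3 channels, g).
#' @export
synthesizeSignals <- function(states, profile = defaultSpectralProfile(),
                              fs = 1000, nEEG = 2, seed = 1) {
  stopifnot(fs >= 250, nEEG >= 2)
  validateSpectralProfile(profile)
  labels <- stateLabels(states)
  spw <- round(windowSeconds(states) * fs)  # samples per state window
  n <- length(labels) * spw
  stateIdx <- rep(match(labels, VIGILANCE_STATES), each = spw)

  getv <- function(field)
    unname(vapply(VIGILANCE_STATES, function(s) profile$states[[s]][[field]],
                  0))

  withSeed(seed, {
    deltaGain <- sqrt(getv("delta"))[stateIdx]
    thetaGain <- sqrt(getv("theta"))[stateIdx]
    bbGain <- sqrt(getv("broadband"))[stateIdx]
    eeg <- matrix(0, n, nEEG)
    for (ch in seq_len(nEEG)) {
      # the broadband floor is flat across the whole record: plain white
      # noise at unit PSD (its sub-0.5 Hz content is high-passed later)
      x <- bandNoiseUnitPSD(n, fs, profile$bands$delta[1],
                            profile$bands$delta[2]) * deltaGain +
           bandNoiseUnitPSD(n, fs, profile$bands$theta[1],
                            profile$bands$theta[2]) * thetaGain +
           rnorm(n) * sqrt(fs / 2) * bbGain
      if (profile$onef$amp1Hz > 0)
        x <- x + onefNoise(n, fs, profile$onef$exponent, profile$onef$amp1Hz)
      eeg[, ch] <- x
    }
    colnames(eeg) <- paste0("EEG", seq_len(nEEG))

    emgTone <- getv("emg")[stateIdx]
    tt <- (seq_len(n) - 1) / fs
    common <- 20 * sin(2 * pi * 50 * tt) + 10 * sin(2 * pi * 0.05 * tt)
    d <- rnorm(n) * emgTone
    emg <- cbind(EMG1 = common + d / 2, EMG2 = common - d / 2)

    accTone <- getv("accel")[stateIdx]
    accel <- matrix(rnorm(3 * n), n, 3) * accTone
    colnames(accel) <- c("AX", "AY", "AZ")

    list(eeg = TimeSeries(eeg, fs, units = "uV"),
         emg = TimeSeries(emg, fs, units = "uV"),
         accel = TimeSeries(accel, fs, units = "g"))
  })
}

#' Synthesize a calcium fluorescence trace with known events
#'
#' Events are Poisson within each state window at the per-state rate;
#' each event adds an instantaneous-rise, exponentially decaying
#' transient with amplitude drawn uniformly from \code{amplitudeRange}
#' (defaults comfortably above the detection criteria so ground truth is
#' recoverable). Polynomial drift and white noise are added on top.
#'
#' @param states a [Hypnogram-class] defining per-window state.
#' @param rates named per-state event rates in events/min
#'   (names WAKE/NREM/REM).
#' @param fs trace sampling rate in Hz.
#' @param tauDecay transient decay time constant in seconds (> 0).
#' @param amplitudeRange range of event amplitudes in dF/F units.
#' @param noiseSd white noise SD in dF/F units.
#' @param driftPoly polynomial drift coefficients (intercept first), in
#'   dF/F units per power of time-in-hours.
#' @param seed integer seed.
#' @return list with \code{trace} (numeric dF/F vector), \code{fs},
#'   \code{eventTimes} (true event times in s) and
#'   \code{eventAmplitudes}.
#' @export
synthesizeCalcium <- function(states,
                              rates = c(WAKE = 0.0677, NREM = 0.5076,
                                        REM = 0.2437),
                              fs = 4, tauDecay = 1.5,
                              amplitudeRange = c(1.5, 3.0), noiseSd = 0.1,
                              driftPoly = c(0, 0.2), seed = 1) {
  stopifnot(all(rates >= 0), tauDecay > 0, fs > 0)
  rates <- rates[VIGILANCE_STATES]
  if (anyNA(rates)) stop("rates must be named with WAKE, NREM, REM")
  labels <- stateLabels(states)
  winS <- windowSeconds(states)
  durS <- length(labels) * winS
  n <- round(durS * fs)
  tGrid <- (seq_len(n) - 1) / fs

  withSeed(seed, {
    perWin <- rpois(length(labels), rates[labels] * winS / 60)
    eventTimes <- numeric(0)
    for (w in which(perWin > 0)) {
      eventTimes <- c(eventTimes,
                      (w - 1) * winS + runif(perWin[w]) * winS)
    }
    eventTimes <- sort(eventTimes)
    amps <- runif(length(eventTimes), amplitudeRange[1], amplitudeRange[2])
    trace <- numeric(n)
    for (k in seq_along(eventTimes)) {
      i0 <- floor(eventTimes[k] * fs) + 1L
      if (i0 > n) next
      idx <- i0:min(n, i0 + ceiling(10 * tauDecay * fs))
      trace[idx] <- trace[idx] +
        amps[k] * exp(-(tGrid[idx] - eventTimes[k]) / tauDecay)
    }
    drift <- outer(tGrid / 3600, seq_along(driftPoly) - 1, "^") %*% driftPoly
    trace <- trace + drop(drift) + rnorm(n, sd = noiseSd)
    list(trace = trace, fs = fs, eventTimes = eventTimes,
         eventAmplitudes = amps)
  })
}

#' Integrate the linear resonant membrane
#'
#' Integrates the two-variable linear membrane
#' \deqn{C dv/dt = -g_L v - w + i(t), \quad \tau_w dw/dt = g_1 v - w}
#' from rest (v = w = 0) using the exact matrix-exponential update for a
#' piecewise-constant stimulus, so the discretization is stable and
#' accurate for any dt satisfying the stated preconditions.
#'
#' @param params a [MembraneParams()] list.
#' @param stimulus injected current trace in pA.
#' @param dt time step in ms; must satisfy dt < tauW/10 and dt < (C/gL)/10.
#' @return voltage trace in mV (deviation from rest), same length as
#'   \code{stimulus}.
#' @examples
#' p <- MembraneParams(gL = 10, C = 150)
#' v <- simulateMembrane(p, rep(100, 5000), dt = 0.1)
#' max(v)  # approaches I/gL = 10 mV
#' @export
simulateMembrane <- function(params, stimulus, dt) {
  stopifnot(inherits(params, "MembraneParams"))
  tauM <- params$C / params$gL
  if (dt >= params$tauW / 10 || dt >= tauM / 10)
    stop(sprintf(
      "dt = %g ms too coarse: need dt < tauW/10 = %g and dt < (C/gL)/10 = %g",
      dt, params$tauW / 10, tauM / 10))
  A <- matrix(c(-params$gL / params$C, -1 / params$C,
                params$g1 / params$tauW, -1 / params$tauW),
              2, 2, byrow = TRUE)
  B <- c(1 / params$C, 0)
  eg <- eigen(A)
  Vi <- solve(eg$vectors)
  Ad <- Re(eg$vectors %*% diag(exp(eg$values * dt)) %*% Vi)
  Bd <- drop(Re(eg$vectors %*% diag((exp(eg$values * dt) - 1) /
                                      eg$values) %*% Vi) %*% B)
  nS <- length(stimulus)
  v <- numeric(nS)
  x1 <- 0; x2 <- 0
  a11 <- Ad[1, 1]; a12 <- Ad[1, 2]; a21 <- Ad[2, 1]; a22 <- Ad[2, 2]
  b1 <- Bd[1]; b2 <- Bd[2]
  for (t in seq_len(nS)) {
    s <- stimulus[t]
    nx1 <- a11 * x1 + a12 * x2 + b1 * s
    x2 <- a21 * x1 + a22 * x2 + b2 * s
    x1 <- nx1
    v[t] <- x1
  }
  v
}

#' Closed-form impedance of the linear resonant membrane
#'
#' \deqn{|Z(f)| = \left| g_L + i 2\pi f C + \frac{g_1}{1 + i 2\pi f \tau_w}
#'   \right|^{-1}}
#' with gL, g1 in nS, C in pF and tauW in ms; returned in megaohms.
#' Serves as the analytic oracle for chirp-based impedance estimates.
#' At DC, \eqn{|Z(0)| = 1/(g_L + g_1)}.
#'
#' @param params a [MembraneParams()] list.
#' @param freqs frequencies in Hz.
#' @return impedance magnitudes in megaohms.
#' @export
analyticImpedance <- function(params, freqs) {
  stopifnot(inherits(params, "MembraneParams"))
  w <- 2 * pi * freqs
  den <- params$gL + 1i * w * params$C * 1e-3 +
    params$g1 / (1 + 1i * w * params$tauW * 1e-3)
  1000 / Mod(den)
}

#' Resonant frequency of the analytic impedance
#'
#' Numerically maximizes [analyticImpedance()] over a band.
#'
#' @param params a [MembraneParams()] list.
#' @param band frequency band in Hz to search.
#' @return frequency of maximal impedance in Hz.
#' @export
analyticResonantFrequency <- function(params, band = c(0.01, 40)) {
  opt <- optimize(function(f) analyticImpedance(params, f),
                  interval = band, maximum = TRUE, tol = 1e-6)
  opt$maximum
}

#' Generate a full synthetic recording session
#'
#' Convenience wrapper chaining [simulateStateSequence()],
#' [synthesizeSignals()] and [synthesizeCalcium()] into one
#' [SyntheticSession-class] with aligned ground truth. Sub-seeds for the
#' three generators are derived deterministically from \code{seed}.
#'
#' @param subject subject identifier.
#' @param durationS session duration in seconds.
#' @param windowS state window in seconds.
#' @param transitionMatrix,dwellWindows passed to [simulateStateSequence()].
#' @param profile passed to [synthesizeSignals()].
#' @param fs acquisition rate in Hz.
#' @param nCells number of calcium cells to synthesize.
#' @param calciumRates per-state rates passed to [synthesizeCalcium()].
#' @param calciumNoiseSd calcium noise SD in dF/F.
#' @param seed integer master seed.
#' @return A [SyntheticSession-class].
#' @export
simulateSession <- function(subject = "s1", durationS = 7200, windowS = 2.5,
                            transitionMatrix = defaultTransitionMatrix(),
                            dwellWindows = 60,
                            profile = defaultSpectralProfile(),
                            fs = 1000, nCells = 8,
                            calciumRates = c(WAKE = 0.0677, NREM = 0.5076,
                                             REM = 0.2437),
                            calciumNoiseSd = 0.1, seed = 1) {
  seed <- as.integer(seed)
  nWindows <- floor(durationS / windowS)
  states <- simulateStateSequence(transitionMatrix, dwellWindows, nWindows,
                                  windowS, seed = seed)
  sig <- synthesizeSignals(states, profile, fs = fs, seed = seed + 1000L)
  calFs <- 4
  traces <- matrix(0, nrow = round(nWindows * windowS * calFs),
                   ncol = nCells)
  events <- vector("list", nCells)
  for (ci in seq_len(nCells)) {
    cal <- synthesizeCalcium(states, rates = calciumRates, fs = calFs,
                             noiseSd = calciumNoiseSd,
                             seed = seed + 2000L + ci)
    traces[, ci] <- cal$trace
    events[[ci]] <- cal$eventTimes
  }
  if (nCells > 0) colnames(traces) <- paste0("cell", seq_len(nCells))
  new("SyntheticSession",
      eeg = sig$eeg, emg = sig$emg, accel = sig$accel, states = states,
      calcium = traces, calciumFs = calFs, calciumEvents = events,
      subject = subject, seed = seed)
}
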