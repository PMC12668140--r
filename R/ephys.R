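# Intrinsic-property extraction from patch-clamp sweeps: chirp (ZAP)
# impedance, resonance metrics and ET-like classification, subthreshold
# step metrics, suprathreshold spike metrics.

#' Exponential (log-frequency) chirp current
#'
#' Sinusoidal current whose instantaneous frequency rises
#' logarithmically from f0 to f1 over T seconds:
#' \deqn{\varphi(t) = 2\pi f_0 T/\ln(f_1/f_0)\,(e^{t \ln(f_1/f_0)/T} - 1)}
#' so the instantaneous frequency is f0 at t = 0, f1 at t = T, and the
#' geometric mean sqrt(f0 f1) at t = T/2.
#'
#' @param f0,f1 start and end frequency in Hz (f1 > f0 > 0).
#' @param T sweep duration in seconds.
#' @param amplitude peak current in pA.
#' @param dt sample interval in ms.
#' @param padS zero-current tail appended after the sweep, in seconds.
#'   Recording through the response decay removes the spectral leakage
#'   that would otherwise bias the impedance estimate near broad peaks.
#' @return list with \code{current} (pA), \code{time} (s), \code{dt}
#'   (ms) and \code{instFreq} (Hz; NA over the tail).
#' @export
makeChirp <- function(f0 = 0.2, f1 = 40, T = 20, amplitude = 50, dt = 0.1,
                      padS = 1) {
  stopifnot(f1 > f0, f0 > 0, T > 0, dt > 0, padS >= 0)
  tt <- seq(0, T, by = dt / 1000)
  r <- log(f1 / f0) / T
  phase <- 2 * pi * f0 / r * (exp(r * tt) - 1)
  cur <- amplitude * sin(phase)
  freq <- f0 * exp(r * tt)
  nPad <- round(padS * 1000 / dt)
  if (nPad > 0) {
    cur <- c(cur, rep(0, nPad))
    freq <- c(freq, rep(NA_real_, nPad))
    tt <- c(tt, max(tt) + seq_len(nPad) * dt / 1000)
  }
  list(current = cur, time = tt, dt = dt, instFreq = freq)
}

#' Impedance amplitude profile (ZAP) from a chirp sweep
#'
#' |Z|(f) = |FFT(V)| / |FFT(I)| evaluated over the stimulated band, in
#' megaohms for voltage in mV and current in pA.
#'
#' @param stimulus injected current trace in pA.
#' @param response voltage response in mV (deviation from rest).
#' @param dt sample interval in ms.
#' @param band frequency band in Hz to retain.
#' @param smooth apply 3-point median smoothing to the profile
#'   (default FALSE: raw ratio).
#' @return an [ImpedanceProfile-class].
#' @export
impedanceProfile <- function(stimulus, response, dt, band = c(0.2, 40),
                             smooth = FALSE) {
  stopifnot(length(stimulus) == length(response), dt > 0)
  n <- length(stimulus)
  fs <- 1000 / dt
  freqs <- (seq_len(n) - 1) * fs / n
  df <- fs / n
  sel <- freqs >= band[1] - df / 2 & freqs <= band[2] + df / 2
  if (!any(sel)) stop("no frequency bins inside the requested band")
  FI <- fft(stimulus)[sel]
  FV <- fft(response)[sel]
  magI <- Mod(FI)
  if (max(magI) <= 0 || min(magI) < 1e-9 * max(magI))
    stop("stimulus spectrum vanishes inside the band; cannot form ratio")
  z <- Mod(FV) / magI * 1000  # mV/pA = GOhm -> MOhm
  if (smooth && length(z) >= 3) z <- stats::runmed(z, 3)
  new("ImpedanceProfile", frequencies = freqs[sel],
      impedance = as.numeric(z))
}

#' Resonance metrics of an impedance profile
#'
#' fR is the frequency of maximal impedance; resonance strength is the
#' ratio of the maximum impedance to the impedance at 0.5 Hz (linear
#' interpolation); the 3 dB cutoff is the first frequency above fR at
#' which |Z| falls to sqrt(0.5) of the maximum (flagged at the band
#' edge if no crossing occurs). All three are invariant under positive
#' rescaling of |Z|.
#'
#' @param z an [ImpedanceProfile-class].
#' @param strengthRefHz reference frequency for resonance strength.
#' @return list with \code{fR} (Hz), \code{strength}, \code{f3dB} (Hz),
#'   \code{f3dBAtBandEdge} (logical).
#' @export
resonanceMetrics <- function(z, strengthRefHz = 0.5) {
  stopifnot(is(z, "ImpedanceProfile"))
  f <- frequencyGrid(z)
  zz <- impedanceValues(z)
  iMax <- which.max(zz)
  fR <- f[iMax]
  zMax <- zz[iMax]
  if (strengthRefHz >= min(f) && strengthRefHz <= max(f)) {
    zRef <- stats::approx(f, zz, xout = strengthRefHz)$y
    strength <- zMax / zRef
  } else {
    warning("profile does not cover ", strengthRefHz,
            " Hz; strength undefined")
    strength <- NA_real_
  }
  target <- sqrt(0.5) * zMax
  above <- which(f > fR & zz <= target)
  if (length(above)) {
    i <- above[1]
    # linear interpolation between the last supra and first sub sample
    f3 <- if (i > 1 && zz[i - 1] > target)
      stats::approx(zz[(i - 1):i], f[(i - 1):i], xout = target)$y
    else f[i]
    atEdge <- FALSE
  } else {
    f3 <- max(f)
    atEdge <- TRUE
  }
  list(fR = fR, strength = strength, f3dB = f3, f3dBAtBandEdge = atEdge)
}

#' Classify ET-like physiology by resonant frequency
#'
#' Resonant frequencies strictly above the threshold (default 2 Hz,
#' the high-delta band boundary) are designated ET-like
#' (extratelencephalic layer-5 physiology).
#'
#' @param fR resonant frequency(ies) in Hz.
#' @param threshold classification threshold in Hz (strict inequality).
#' @return logical vector.
#' @export
classifyET <- function(fR, threshold = 2) {
  fR > threshold
}

# Spike detection: local maxima above an absolute voltage criterion,
# separated by at least refractMs.
detectSpikes <- function(v, dt, peakMin = 0, refractMs = 2) {
  d <- diff(v)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[v[cand] >= peakMin]
  if (length(cand) > 1) {
    # collapse bursts of samples within the refractory window
    out <- integer(0)
    last <- -Inf
    for (i in cand) {
      if ((i - last) * dt >= refractMs) {
        out <- c(out, i)
        last <- i
      } else if (v[i] > v[out[length(out)]]) {
        out[length(out)] <- i
        last <- i
      }
    }
    cand <- out
  }
  cand
}

#' Subthreshold step metrics: input resistance, sag, rebound
#'
#' From a family of 1 s square current steps (canonically 11 steps,
#' -150 to +50 pA in 20 pA increments): maximum input resistance from
#' the slope of the peak voltage deflection versus current, steady-state
#' input resistance from the slope of the mean deflection over the final
#' \code{steadyMs} of the step, sag ratio = Rin_max / Rin_steady, and
#' rebound slope from regressing the post-offset rebound amplitude on
#' the steady-state membrane potential. Slopes use the linear
#' (hyperpolarizing, current <= \code{linearMaxPA}) portion of the I-V
#' relation. Sweeps containing spikes are excluded.
#'
#' @param currents step amplitude per sweep in pA.
#' @param voltages matrix (time x sweep) of voltage responses in mV
#'   (deviation from the pre-step baseline, or absolute; the pre-step
#'   baseline is subtracted internally).
#' @param dt sample interval in ms.
#' @param stepStartS,stepDurS step onset and duration in seconds.
#' @param steadyMs length of the steady-state window at the end of the
#'   step, in ms.
#' @param linearMaxPA only sweeps with current <= this bound enter the
#'   resistance fits.
#' @param reboundWinMs window after step offset searched for the rebound
#'   extremum.
#' @return list with \code{RinMax}, \code{RinSteady} (MOhm), \code{sag},
#'   \code{reboundSlope}, \code{perSweep} data.frame,
#'   \code{excludedSweeps}.
#' @export
subthresholdStepMetrics <- function(currents, voltages, dt,
                                    stepStartS = 0.2, stepDurS = 1,
                                    steadyMs = 200, linearMaxPA = -10,
                                    reboundWinMs = 400) {
  voltages <- as.matrix(voltages)
  stopifnot(length(currents) == ncol(voltages))
  fsm <- 1 / dt  # samples per ms
  i0 <- round(stepStartS * 1000 * fsm) + 1L
  i1 <- round((stepStartS + stepDurS) * 1000 * fsm)
  iSteady <- round((stepStartS * 1000 + stepDurS * 1000 - steadyMs) * fsm) + 1L
  n <- nrow(voltages)
  per <- data.frame(current = currents, peak = NA_real_,
                    steady = NA_real_, rebound = NA_real_,
                    spikes = 0L)
  for (s in seq_along(currents)) {
    v <- voltages[, s]
    base <- mean(v[seq_len(max(1L, i0 - 1L))])
    vd <- v - base
    sp <- detectSpikes(vd, dt, peakMin = 40)  # spikes tower over steps
    per$spikes[s] <- length(sp)
    seg <- vd[i0:min(i1, n)]
    per$peak[s] <- seg[which.max(abs(seg))]
    per$steady[s] <- mean(vd[iSteady:min(i1, n)])
    post <- vd[min(i1 + 1L, n):min(i1 + round(reboundWinMs * fsm), n)]
    # signed overshoot: h-current rebound is depolarizing after
    # hyperpolarizing steps; an ohmic cell relaxes to ~0 with no overshoot
    per$rebound[s] <- max(post)
  }
  ok <- per$spikes == 0
  lin <- ok & currents <= linearMaxPA
  if (sum(lin) < 2) stop("need >= 2 spike-free hyperpolarizing sweeps")
  RinMax <- unname(stats::coef(stats::lm(peak ~ current,
                                         data = per[lin, ]))[2]) * 1000
  RinSteady <- unname(stats::coef(stats::lm(steady ~ current,
                                            data = per[lin, ]))[2]) * 1000
  rebSlope <- unname(stats::coef(stats::lm(rebound ~ steady,
                                           data = per[lin, ]))[2])
  list(RinMax = RinMax, RinSteady = RinSteady, sag = RinMax / RinSteady,
       reboundSlope = rebSlope, perSweep = per,
       excludedSweeps = which(!ok))
}

#' Suprathreshold spike metrics
#'
#' From a family of 1 s depolarizing steps of increasing amplitude:
#' rheobase (minimal current with >= 1 spike); from the first spike at
#' rheobase the voltage threshold (first point where dV/dt exceeds
#' 20 V/s), maximum and minimum dV/dt, and half-width (width at half the
#' amplitude between threshold and peak); the first interspike interval
#' at the minimal current driving >= 2 spikes; and spike-frequency
#' accommodation (second ISI / last ISI) from the first train with
#' >= 10 spikes. Metrics whose defining sweep does not exist are NA.
#'
#' @param currents step amplitude per sweep in pA (increasing order).
#' @param voltages matrix (time x sweep) in mV.
#' @param dt sample interval in ms.
#' @param thresholdSlope dV/dt criterion in V/s (= mV/ms).
#' @param spikePeakMin minimum absolute peak voltage for spike
#'   detection, in mV.
#' @return list with \code{rheobase}, \code{apThreshold},
#'   \code{maxDvdt}, \code{minDvdt}, \code{halfWidth}, \code{firstISI},
#'   \code{SFA}, \code{spikeCounts}.
#' @export
suprathresholdMetrics <- function(currents, voltages, dt,
                                  thresholdSlope = 20, spikePeakMin = 0) {
  voltages <- as.matrix(voltages)
  stopifnot(length(currents) == ncol(voltages))
  ord <- order(currents)
  currents <- currents[ord]
  voltages <- voltages[, ord, drop = FALSE]
  spk <- lapply(seq_along(currents), function(s)
    detectSpikes(voltages[, s], dt, peakMin = spikePeakMin))
  counts <- lengths(spk)
  out <- list(rheobase = NA_real_, apThreshold = NA_real_,
              maxDvdt = NA_real_, minDvdt = NA_real_,
              halfWidth = NA_real_, firstISI = NA_real_, SFA = NA_real_,
              spikeCounts = stats::setNames(counts, currents))
  iRheo <- which(counts >= 1)[1]
  if (is.na(iRheo)) return(out)
  out$rheobase <- currents[iRheo]
  v <- voltages[, iRheo]
  p <- spk[[iRheo]][1]
  dvdt <- c(NA, diff(v)) / dt  # mV/ms = V/s
  # walk back from the peak to the first threshold-slope crossing
  iThr <- p
  while (iThr > 2 && !is.na(dvdt[iThr - 1]) && dvdt[iThr - 1] >=
         thresholdSlope) iThr <- iThr - 1
  if (!is.na(dvdt[iThr]) && dvdt[iThr] >= thresholdSlope) {
    # take-off point: the sample whose forward slope first exceeds the
    # criterion (one before the first supra-threshold backward slope)
    iThr <- max(1L, iThr - 1L)
    out$apThreshold <- v[iThr]
    win <- max(1, iThr - round(1 / dt)):min(length(v), p + round(5 / dt))
    out$maxDvdt <- max(dvdt[win], na.rm = TRUE)
    out$minDvdt <- min(dvdt[win], na.rm = TRUE)
    half <- (out$apThreshold + v[p]) / 2
    iUp <- iThr
    while (iUp < p && v[iUp] < half) iUp <- iUp + 1L
    tUp <- if (iUp > 1 && v[iUp] != v[iUp - 1])
      iUp - 1 + (half - v[iUp - 1]) / (v[iUp] - v[iUp - 1]) else iUp
    iDn <- p
    nEnd <- min(length(v), p + round(10 / dt))
    while (iDn < nEnd && v[iDn] > half) iDn <- iDn + 1L
    tDn <- if (iDn > p && v[iDn] != v[iDn - 1])
      iDn - 1 + (half - v[iDn - 1]) / (v[iDn] - v[iDn - 1]) else iDn
    out$halfWidth <- (tDn - tUp) * dt
  }
  iTwo <- which(counts >= 2)[1]
  if (!is.na(iTwo)) {
    st <- spk[[iTwo]]
    out$firstISI <- (st[2] - st[1]) * dt
  }
  iTen <- which(counts >= 10)[1]
  if (!is.na(iTen)) {
    isi <- diff(spk[[iTen]]) * dt
    out$SFA <- isi[2] / isi[length(isi)]
  }
  out
}
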