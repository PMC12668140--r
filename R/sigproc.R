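# Deterministic signal conditioning and spectral estimation.
# All filters are applied forward-backward (zero phase).

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first k Slepian sequences of length n with time-bandwidth
#' product nw, via the eigenvectors of the classical symmetric
#' tridiagonal commuting matrix. Tapers are returned with unit energy
#' and a positive-mean sign convention.
#'
#' @param n sequence length in samples.
#' @param nw time-bandwidth product (half-bandwidth is nw/n cycles/sample).
#' @param k number of tapers (k <= 2*nw - 1 recommended).
#' @return n x k matrix, one taper per column.
#' @export
dpssTapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  W <- nw / n
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- dg
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  v <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  v
}

# Zero-phase Butterworth. The mean is removed before filtering and, for
# low-pass filters, restored afterwards: a high-pass has zero DC gain
# and a low-pass unit DC gain, so this is exact for the DC component and
# avoids the start-up transients of filtering a large offset.
butterFiltFilt <- function(x, order, cutoffHz, fs, type) {
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = type)
  m <- mean(x)
  y <- signal::filtfilt(bf, x - m)
  if (type == "low") y + m else y
}

# Anti-aliased decimation by integer factor q: zero-phase Butterworth
# low-pass at 80% of the target Nyquist, then subsampling.
decimateChannel <- function(x, fs, q) {
  y <- butterFiltFilt(x, order = 8, cutoffHz = 0.8 * (fs / q) / 2, fs = fs,
                      type = "low")
  y[seq(1, length(y), by = q)]
}

#' Preprocess EEG: decimate, high-pass, mean re-reference
#'
#' Decimates 1 kHz EEG to 125 Hz with an anti-aliasing low-pass,
#' applies a 4th-order Butterworth high-pass at 0.5 Hz forward-backward
#' (zero phase), and subtracts the per-sample mean across channels.
#'
#' @param raw a [TimeSeries-class] at 1000 Hz with >= 2 channels.
#' @param targetFs target rate in Hz (must divide the input rate).
#' @param highpassHz high-pass cutoff in Hz.
#' @return a [TimeSeries-class] at \code{targetFs}.
#' @export
preprocessEEG <- function(raw, targetFs = 125, highpassHz = 0.5) {
  stopifnot(is(raw, "TimeSeries"))
  if (abs(samplingRate(raw) - 1000) > 1e-9)
    stop("preprocessEEG expects 1000 Hz input, got ", samplingRate(raw), " Hz")
  if (ncol(raw@samples) < 2)
    stop("mean re-referencing requires >= 2 EEG channels")
  q <- samplingRate(raw) / targetFs
  if (abs(q - round(q)) > 1e-9) stop("targetFs must divide the input rate")
  q <- as.integer(round(q))
  dec <- apply(raw@samples, 2, decimateChannel, fs = samplingRate(raw), q = q)
  hp <- apply(dec, 2, butterFiltFilt, order = 4, cutoffHz = highpassHz,
              fs = targetFs, type = "high")
  reref <- hp - rowMeans(hp)
  colnames(reref) <- colnames(raw@samples)
  TimeSeries(reref, targetFs, units = raw@units, startTime = raw@startTime)
}

#' Preprocess EMG: differential reference and high-pass
#'
#' Takes the difference of an EMG electrode pair (removing common-mode
#' artifact) and applies a 4th-order Butterworth high-pass at 300 Hz
#' forward-backward.
#'
#' @param raw a [TimeSeries-class] at 1000 Hz.
#' @param pair indices of the two EMG channels.
#' @param highpassHz high-pass cutoff in Hz.
#' @return single-channel [TimeSeries-class] at the input rate.
#' @export
preprocessEMG <- function(raw, pair = c(1, 2), highpassHz = 300) {
  stopifnot(is(raw, "TimeSeries"))
  if (abs(samplingRate(raw) - 1000) > 1e-9)
    stop("preprocessEMG expects 1000 Hz input")
  if (length(pair) != 2 || ncol(raw@samples) < 2)
    stop("differential referencing requires exactly 2 EMG channels")
  d <- raw@samples[, pair[1]] - raw@samples[, pair[2]]
  out <- butterFiltFilt(d, order = 4, cutoffHz = highpassHz,
                        fs = samplingRate(raw), type = "high")
  TimeSeries(matrix(out, ncol = 1, dimnames = list(NULL, "EMG")),
             samplingRate(raw), units = raw@units, startTime = raw@startTime)
}

# Shared window grid: window k covers [(k-1)*stepS, (k-1)*stepS + windowS],
# center at windowS/2 + (k-1)*stepS. Partial trailing windows are dropped.
windowGrid <- function(nSamp, fs, windowS, stepS) {
  nWin <- floor(((nSamp / fs) - windowS) / stepS) + 1
  if (nWin < 1) stop("signal shorter than one analysis window")
  starts <- round((seq_len(nWin) - 1) * stepS * fs) + 1L
  list(nWin = as.integer(nWin), starts = starts,
       lenS = as.integer(round(windowS * fs)),
       centers = windowS / 2 + (seq_len(nWin) - 1) * stepS)
}

#' Multitaper spectrogram
#'
#' Slepian-taper averaged periodograms in sliding windows (defaults:
#' 35 tapers, 5 s window, 2.5 s step). Each window is demeaned, tapered
#' with k unit-energy Slepian sequences, and the one-sided power
#' spectral density is averaged over tapers.
#'
#' @param ts a [TimeSeries-class].
#' @param windowS window length in s.
#' @param stepS step between windows in s.
#' @param nTapers number of Slepian tapers. The default time-bandwidth
#'   product is (nTapers + 1)/2 (K = 2NW - 1).
#' @param nw time-bandwidth product override.
#' @param channel channel index to analyze.
#' @return a [Spectrogram-class]; power in (input units)^2/Hz.
#' @export
multitaperSpectrogram <- function(ts, windowS = 5, stepS = 2.5,
                                  nTapers = 35, nw = (nTapers + 1) / 2,
                                  channel = 1) {
  stopifnot(is(ts, "TimeSeries"))
  fs <- samplingRate(ts)
  x <- ts@samples[, channel]
  g <- windowGrid(length(x), fs, windowS, stepS)
  if (g$lenS < 2 * nTapers)
    stop("window too short for requested taper count (need windowS*fs >= 2*nTapers)")
  tapers <- dpssTapers(g$lenS, nw, nTapers)
  nF <- g$lenS %/% 2 + 1
  freqs <- (seq_len(nF) - 1) * fs / g$lenS
  P <- matrix(0, g$nWin, nF)
  for (w in seq_len(g$nWin)) {
    seg <- x[g$starts[w]:(g$starts[w] + g$lenS - 1L)]
    seg <- seg - mean(seg)
    ft <- stats::mvfft(tapers * seg)
    p <- rowMeans(Mod(ft[seq_len(nF), , drop = FALSE])^2) / fs
    # one-sided density: double all bins except DC (and Nyquist if even n)
    dbl <- rep(2, nF)
    dbl[1] <- 1
    if (g$lenS %% 2 == 0) dbl[nF] <- 1
    P[w, ] <- p * dbl
  }
  new("Spectrogram", power = P, frequencies = freqs,
      windowCenters = g$centers, windowS = windowS, stepS = stepS,
      nTapers = nTapers)
}

#' Windowed root-mean-square
#'
#' RMS per window on the same window grid as [multitaperSpectrogram()],
#' pooling all channels (for 3-axis accelerometer data this is the RMS
#' of the joint deflection).
#'
#' @param ts a [TimeSeries-class].
#' @param windowS,stepS window grid in seconds.
#' @param demean subtract the channel mean before squaring.
#' @return data.frame with columns \code{windowCenter} (s) and \code{rms}.
#' @export
windowedRMS <- function(ts, windowS = 5, stepS = 2.5, demean = FALSE) {
  stopifnot(is(ts, "TimeSeries"))
  fs <- samplingRate(ts)
  x <- ts@samples
  if (demean) x <- sweep(x, 2, colMeans(x))
  g <- windowGrid(nrow(x), fs, windowS, stepS)
  vals <- vapply(seq_len(g$nWin), function(w) {
    seg <- x[g$starts[w]:(g$starts[w] + g$lenS - 1L), , drop = FALSE]
    sqrt(mean(seg^2))
  }, 0)
  data.frame(windowCenter = g$centers, rms = vals)
}

#' Band power fraction (slow-wave activity)
#'
#' Per-window fraction of spectral power inside a band relative to a
#' total band, integrating the power spectral density over frequency
#' bins whose centers fall inside each (inclusive) band. With the
#' defaults this is slow-wave activity: the fraction of 0.5-4 Hz power
#' relative to all retained power (0.5 Hz high-pass to the 62.5 Hz
#' Nyquist of the decimated record).
#'
#' @param spec a [Spectrogram-class].
#' @param band numerator band in Hz.
#' @param totalBand denominator band in Hz (must contain \code{band}).
#' @return data.frame with columns \code{windowCenter} and
#'   \code{fraction} (each in [0, 1]).
#' @export
bandFraction <- function(spec, band = c(0.5, 4), totalBand = c(0.5, 62.5)) {
  stopifnot(is(spec, "Spectrogram"))
  if (band[2] <= band[1]) stop("empty band")
  if (band[1] < totalBand[1] || band[2] > totalBand[2])
    stop("band must lie within totalBand")
  f <- frequencyGrid(spec)
  inBand <- f >= band[1] & f <= band[2]
  inTotal <- f >= totalBand[1] & f <= totalBand[2]
  if (!any(inBand)) stop("no frequency bins inside band")
  num <- rowSums(powerMatrix(spec)[, inBand, drop = FALSE])
  den <- rowSums(powerMatrix(spec)[, inTotal, drop = FALSE])
  frac <- ifelse(den > 0, num / den, 0)
  data.frame(windowCenter = windowCenters(spec), fraction = frac)
}

#' Per-frequency spectral power ratio
#'
#' Ratio of window-averaged power between two spectrograms on identical
#' frequency grids (e.g. post- vs pre-intervention). Frequencies with
#' zero pre power yield NA and are flagged in the \code{undefined}
#' column rather than causing an error.
#'
#' @param specPost,specPre [Spectrogram-class] objects on the same
#'   frequency grid.
#' @return data.frame with columns \code{frequency}, \code{ratio},
#'   \code{undefined}.
#' @export
powerRatio <- function(specPost, specPre) {
  stopifnot(is(specPost, "Spectrogram"), is(specPre, "Spectrogram"))
  if (length(frequencyGrid(specPost)) != length(frequencyGrid(specPre)) ||
      max(abs(frequencyGrid(specPost) - frequencyGrid(specPre))) > 1e-9)
    stop("spectrograms must share an identical frequency grid")
  post <- colMeans(powerMatrix(specPost))
  pre <- colMeans(powerMatrix(specPre))
  undef <- pre <= 0
  ratio <- ifelse(undef, NA_real_, post / pre)
  data.frame(frequency = frequencyGrid(specPost), ratio = ratio,
             undefined = undef)
}

#' Body-temperature trace from thermal frames
#'
#' Identifies the animal as the hottest fraction of pixels in each frame
#' (default hottest 1%), takes their median temperature, and smooths the
#' resulting series with a moving median (default 5 min) to remove
#' single-frame artifacts. Optionally re-expresses the trace relative to
#' the mean over a reference period.
#'
#' @param frames numeric array (height x width x frames) in degrees C.
#' @param fs frame rate in Hz.
#' @param hotFraction fraction of hottest pixels defining the animal.
#' @param smoothS moving-median span in seconds.
#' @param refRange optional c(start, end) in seconds; if given, the mean
#'   over this period is subtracted.
#' @return data.frame with columns \code{time} (s) and \code{temperature}.
#' @export
thermalTrace <- function(frames, fs = 0.1, hotFraction = 0.01,
                         smoothS = 300, refRange = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1)
  nf <- dim(frames)[3]
  nHot <- max(1L, ceiling(hotFraction * prod(dim(frames)[1:2])))
  raw <- vapply(seq_len(nf), function(i) {
    px <- as.vector(frames[, , i])
    stats::median(sort(px, decreasing = TRUE)[seq_len(nHot)])
  }, 0)
  k <- round(smoothS * fs)
  if (k %% 2 == 0) k <- k + 1
  sm <- if (k >= 3 && nf >= k) as.numeric(stats::runmed(raw, k)) else raw
  tt <- (seq_len(nf) - 1) / fs
  if (!is.null(refRange)) {
    sel <- tt >= refRange[1] & tt <= refRange[2]
    if (!any(sel)) stop("reference range not covered by the trace")
    sm <- sm - mean(sm[sel])
  }
  data.frame(time = tt, temperature = sm)
}
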