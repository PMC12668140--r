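#' @import methods
NULL

VIGILANCE_STATES <- c("WAKE", "NREM", "REM")

#' Multichannel time series container
#'
#' Holds regularly sampled multichannel signals (EEG, EMG, accelerometer,
#' temperature, ...) as a time-by-channel matrix with a sampling rate and
#' physical units.
#'
#' @slot samples numeric matrix, time points in rows, channels in columns.
#'   Column names are channel labels.
#' @slot fs sampling rate in Hz.
#' @slot units physical units of the samples (e.g. "uV", "g", "degC").
#' @slot startTime recording start in seconds (time of the first sample).
#'
#' @export
setClass("TimeSeries",
  representation(
    samples = "matrix",
    fs = "numeric",
    units = "character",
    startTime = "numeric"
  ),
  prototype(units = "", startTime = 0)
)

setValidity("TimeSeries", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  else if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeries
#'
#' @param samples numeric vector (single channel) or time-by-channel matrix.
#' @param fs sampling rate in Hz.
#' @param units physical units string.
#' @param startTime time of the first sample in seconds.
#' @return A [TimeSeries-class] object.
#' @examples
#' ts <- TimeSeries(matrix(rnorm(2000), ncol = 2), fs = 1000, units = "uV")
#' nSamples(ts)
#' @export
TimeSeries <- function(samples, fs, units = "", startTime = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  new("TimeSeries", samples = samples, fs = fs, units = units,
      startTime = startTime)
}

#' Time-frequency power container
#'
#' A windowed power spectral estimate: one row per analysis window, one
#' column per frequency bin, with the window grid recorded so that
#' spectral features, RMS series and hypnograms share a common time base.
#'
#' @slot power numeric matrix (window x frequency), power spectral density.
#' @slot frequencies frequency bin centers in Hz, strictly increasing.
#' @slot windowCenters window center times in seconds.
#' @slot windowS window length in seconds.
#' @slot stepS step between consecutive windows in seconds.
#' @slot nTapers number of Slepian tapers averaged per window.
#'
#' @export
setClass("Spectrogram",
  representation(
    power = "matrix",
    frequencies = "numeric",
    windowCenters = "numeric",
    windowS = "numeric",
    stepS = "numeric",
    nTapers = "numeric"
  )
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (ncol(object@power) != length(object@frequencies))
    msg <- c(msg, "ncol(power) must equal length(frequencies)")
  if (nrow(object@power) != length(object@windowCenters))
    msg <- c(msg, "nrow(power) must equal length(windowCenters)")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@windowCenters) > 1) {
    d <- diff(object@windowCenters)
    if (max(abs(d - object@stepS)) > 1e-6)
      msg <- c(msg, "window centers must be uniformly spaced by stepS")
  }
  if (length(msg)) msg else TRUE
})

#' Hypnogram: per-window vigilance labels
#'
#' The backbone that all state-conditioned metrics index into: one label
#' from \{WAKE, NREM, REM\} per window on a fixed grid.
#'
#' @slot labels character vector of per-window labels.
#' @slot windowS seconds per label window (the grid step).
#' @slot provenance one of "raw", "persistence-filtered", "manual",
#'   "simulated".
#'
#' @export
setClass("Hypnogram",
  representation(
    labels = "character",
    windowS = "numeric",
    provenance = "character"
  ),
  prototype(provenance = "raw")
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@labels) < 1L) msg <- c(msg, "labels must be non-empty")
  if (!all(object@labels %in% VIGILANCE_STATES))
    msg <- c(msg, "labels must be drawn from WAKE, NREM, REM")
  if (length(object@windowS) != 1L || object@windowS <= 0)
    msg <- c(msg, "windowS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param labels character vector of per-window labels in
#'   \code{c("WAKE", "NREM", "REM")}.
#' @param windowS seconds per window.
#' @param provenance label provenance tag.
#' @return A [Hypnogram-class] object.
#' @examples
#' h <- Hypnogram(rep(c("WAKE", "NREM"), c(20, 30)), windowS = 2.5)
#' table(stateLabels(h))
#' @export
Hypnogram <- function(labels, windowS = 2.5, provenance = "raw") {
  new("Hypnogram", labels = as.character(labels), windowS = windowS,
      provenance = provenance)
}

#' Simulated vigilance-state sequence with ground truth
#'
#' A [Hypnogram-class] produced by the Markov generator, carrying the
#' bout-level sequence (before expansion onto the window grid) and the
#' seed, so that bout-level transition statistics can be checked against
#' the generating matrix.
#'
#' @slot bouts data.frame with columns \code{state} and \code{windows}
#'   (dwell in windows), one row per bout.
#' @slot seed integer seed used by the generator.
#'
#' @export
setClass("StateSequence",
  contains = "Hypnogram",
  representation(bouts = "data.frame", seed = "integer"),
  prototype(provenance = "simulated")
)

#' Membrane impedance amplitude profile
#'
#' |Z|(f) obtained from the ratio of voltage and current spectra of a
#' chirp (ZAP) stimulus, restricted to the stimulated band.
#'
#' @slot frequencies frequencies in Hz.
#' @slot impedance impedance magnitude in megaohms.
#'
#' @export
setClass("ImpedanceProfile",
  representation(frequencies = "numeric", impedance = "numeric")
)

setValidity("ImpedanceProfile", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@impedance))
    msg <- c(msg, "frequencies and impedance must have equal length")
  if (any(object@impedance < 0)) msg <- c(msg, "impedance must be >= 0")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Linearized membrane parameters
#'
#' Parameters of a two-variable linear membrane: a leaky RC compartment
#' plus one slow negative-feedback branch, the minimal model exhibiting
#' subthreshold resonance of the kind produced by HCN (h-current)
#' channels. The slow branch current w obeys
#' \eqn{\tau_w dw/dt = g_1 v - w} and opposes voltage deflections.
#'
#' @param gL leak conductance in nS (> 0).
#' @param C membrane capacitance in pF (> 0).
#' @param g1 slow-branch gain in nS (>= 0; 0 gives a plain RC membrane).
#' @param tauW slow time constant in ms (> 0).
#' @return A named list of class \code{MembraneParams}.
#' @examples
#' p <- MembraneParams(gL = 10, C = 150, g1 = 30, tauW = 60)
#' @export
MembraneParams <- function(gL, C, g1 = 0, tauW = 50) {
  stopifnot(gL > 0, C > 0, g1 >= 0, tauW > 0)
  structure(list(gL = gL, C = C, g1 = g1, tauW = tauW),
            class = "MembraneParams")
}

#' Synthetic multimodal recording session
#'
#' Ground-truth container produced by the synthetic generator: raw
#' EEG/EMG/accelerometer channels at the acquisition rate, the latent
#' state sequence, and calcium traces with their true event times.
#'
#' @slot eeg,emg,accel [TimeSeries-class] channels sharing one duration.
#' @slot states [StateSequence-class] ground-truth hypnogram.
#' @slot calcium numeric matrix (time x cell) of \eqn{\Delta F/F} traces.
#' @slot calciumFs calcium sampling rate in Hz.
#' @slot calciumEvents list of per-cell true event time vectors (s).
#' @slot subject subject identifier.
#' @slot seed integer seed.
#'
#' @export
setClass("SyntheticSession",
  representation(
    eeg = "TimeSeries",
    emg = "TimeSeries",
    accel = "TimeSeries",
    states = "StateSequence",
    calcium = "matrix",
    calciumFs = "numeric",
    calciumEvents = "list",
    subject = "character",
    seed = "integer"
  )
)

setValidity("SyntheticSession", function(object) {
  msg <- character()
  dur <- function(ts) nrow(ts@samples) / ts@fs
  if (abs(dur(object@eeg) - dur(object@emg)) > 1e-6 ||
      abs(dur(object@eeg) - dur(object@accel)) > 1e-6)
    msg <- c(msg, "eeg, emg and accel must share one duration")
  sdur <- length(object@states@labels) * object@states@windowS
  if (abs(dur(object@eeg) - sdur) > object@states@windowS)
    msg <- c(msg, "state sequence must span the signal duration")
  if (length(msg)) msg else TRUE
})
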