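# Accessor generics and show methods for the data containers.

#' Sampling rate accessor
#' @param x a TimeSeries.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TimeSeries", function(x) x@fs)

#' Sample matrix accessor
#' @param x a TimeSeries.
#' @return the time-by-channel sample matrix.
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))

#' @rdname sampleMatrix
#' @export
setMethod("sampleMatrix", "TimeSeries", function(x) x@samples)

#' Number of samples per channel
#' @param x a TimeSeries.
#' @return integer number of time points.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "TimeSeries", function(x) nrow(x@samples))

#' Per-window state labels of a hypnogram
#' @param x a Hypnogram.
#' @return character vector of labels.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "Hypnogram", function(x) x@labels)

#' Window length (seconds) of a windowed object
#' @param x a Hypnogram or Spectrogram.
#' @return window duration in seconds (for a Hypnogram, the label grid step).
#' @export
setGeneric("windowSeconds", function(x) standardGeneric("windowSeconds"))

#' @rdname windowSeconds
#' @export
setMethod("windowSeconds", "Hypnogram", function(x) x@windowS)

#' @rdname windowSeconds
#' @export
setMethod("windowSeconds", "Spectrogram", function(x) x@windowS)

#' Power matrix of a spectrogram
#' @param x a Spectrogram.
#' @return window-by-frequency power matrix.
#' @export
setGeneric("powerMatrix", function(x) standardGeneric("powerMatrix"))

#' @rdname powerMatrix
#' @export
setMethod("powerMatrix", "Spectrogram", function(x) x@power)

#' Frequency grid accessor
#' @param x a Spectrogram or ImpedanceProfile.
#' @return frequencies in Hz.
#' @export
setGeneric("frequencyGrid", function(x) standardGeneric("frequencyGrid"))

#' @rdname frequencyGrid
#' @export
setMethod("frequencyGrid", "Spectrogram", function(x) x@frequencies)

#' @rdname frequencyGrid
#' @export
setMethod("frequencyGrid", "ImpedanceProfile", function(x) x@frequencies)

#' Window center times of a spectrogram
#' @param x a Spectrogram.
#' @return window centers in seconds.
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))

#' @rdname windowCenters
#' @export
setMethod("windowCenters", "Spectrogram", function(x) x@windowCenters)

#' Impedance magnitude accessor
#' @param x an ImpedanceProfile.
#' @return impedance magnitude in megaohms.
#' @export
setGeneric("impedanceValues", function(x) standardGeneric("impedanceValues"))

#' @rdname impedanceValues
#' @export
setMethod("impedanceValues", "ImpedanceProfile", function(x) x@impedance)

#' Bout table of a simulated state sequence
#' @param x a StateSequence.
#' @return data.frame of generating bouts (state, windows).
#' @export
setGeneric("generatingBouts", function(x) standardGeneric("generatingBouts"))

#' @rdname generatingBouts
#' @export
setMethod("generatingBouts", "StateSequence", function(x) x@bouts)

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples x %d channel(s) @ %g Hz (%.1f s)%s\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              nrow(object@samples) / object@fs,
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d windows x %d frequencies (%.3g-%.3g Hz), %g s window / %g s step, %d tapers\n",
    nrow(object@power), length(object@frequencies),
    min(object@frequencies), max(object@frequencies),
    object@windowS, object@stepS, object@nTapers))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@labels, levels = VIGILANCE_STATES))
  cat(sprintf("Hypnogram (%s): %d windows of %g s\n", object@provenance,
              length(object@labels), object@windowS))
  cat(sprintf("  WAKE %d | NREM %d | REM %d\n", tab["WAKE"], tab["NREM"],
              tab["REM"]))
})

setMethod("show", "ImpedanceProfile", function(object) {
  m <- resonanceMetrics(object)
  cat(sprintf(
    "ImpedanceProfile: %d points, %.3g-%.3g Hz; fR = %.2f Hz, strength = %.2f\n",
    length(object@frequencies), min(object@frequencies),
    max(object@frequencies), m$fR, m$strength))
})

setMethod("show", "SyntheticSession", function(object) {
  cat(sprintf("SyntheticSession '%s' (seed %d)\n", object@subject, object@seed))
  cat(sprintf("  EEG %d ch, EMG %d ch, accel %d ch @ %g Hz, %.1f s\n",
              ncol(object@eeg@samples), ncol(object@emg@samples),
              ncol(object@accel@samples), object@eeg@fs,
              nrow(object@eeg@samples) / object@eeg@fs))
  cat(sprintf("  %d calcium cells @ %g Hz; %d state windows of %g s\n",
              ncol(object@calcium), object@calciumFs,
              length(object@states@labels), object@states@windowS))
})
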