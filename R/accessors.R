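#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn duration duration of a spike train
#' @export
setMethod("duration", "SpikeTrain", function(x) x@duration)

#' @describeIn duration duration of a sweep pair
#' @export
setMethod("duration", "SweepPair", function(x) ncol(x@log2f) * x@dt)

#' @describeIn duration duration of a spectrogram
#' @export
setMethod("duration", "Spectrogram", function(x) ncol(x@energy) * x@dt)

#' @describeIn duration total duration of a tone schedule
#' @export
setMethod("duration", "ToneSchedule",
          function(x) (x@nFreqs * x@nReps) / x@rate)

#' @describeIn ncr NCR of a decoding result
#' @export
setMethod("ncr", "DecodingResult", function(x) x@ncr)

#' @describeIn frequencyCenters centers of a frequency axis
#' @export
setMethod("frequencyCenters", "FrequencyAxis", function(x) x@centers)

#' @describeIn frequencyCenters centers of a spectrogram's axis
#' @export
setMethod("frequencyCenters", "Spectrogram", function(x) x@axis@centers)

#' @describeIn timeStep time step of a spectrogram
#' @export
setMethod("timeStep", "Spectrogram", function(x) x@dt)

#' @describeIn timeStep trajectory step of a sweep pair
#' @export
setMethod("timeStep", "SweepPair", function(x) x@dt)

#' @describeIn timeStep time step of a decoded stimulus
#' @export
setMethod("timeStep", "DecodedStimulus", function(x) x@dt)

#' @describeIn spikeTimes spike times of a spike train
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @describeIn energy energy grid of a spectrogram
#' @export
setMethod("energy", "Spectrogram", function(x) x@energy)

#' @describeIn corrProfile per-dimension profile of a decoding result
#' @export
setMethod("corrProfile", "DecodingResult", function(x, dim = c("time", "frequency")) {
  dim <- match.arg(dim)
  if (dim == "time") x@corrT else x@corrF
})

#' @describeIn threshold calibrated threshold
#' @export
setMethod("threshold", "NullCalibration", function(x) x@threshold)

#' @describeIn normalizedSynergy normalized synergy of a decomposition
#' @export
setMethod("normalizedSynergy", "PairDecomposition", function(x) x@normalizedSynergy)

#' @describeIn strfFeatures feature record of an STRF
#' @export
setMethod("strfFeatures", "STRF", function(x) x@features)

## show methods -------------------------------------------------------------

setMethod("show", "FrequencyAxis", function(object) {
  ctr <- object@centers
  cat(sprintf("FrequencyAxis: %d channels, %.3g-%.3g kHz (%.2f octaves)\n",
              length(ctr), ctr[1] / 1e3, ctr[length(ctr)] / 1e3,
              log2(ctr[length(ctr)] / ctr[1])))
})

setMethod("show", "SweepPair", function(object) {
  cat(sprintf("SweepPair: 2 voices, %.1f s at dt = %.4g s, band %.3g-%.3g kHz, FM < %g Hz (seed %d)\n",
              duration(object), object@dt, object@bounds[1] / 1e3,
              object@bounds[2] / 1e3, object@speedCutoff, object@seed))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d channels x %d bins (%.1f s at dt = %.4g s)\n",
              nrow(object@energy), ncol(object@energy), duration(object),
              object@dt))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (%.2f sp/s)\n",
              object@unitId, length(object@times), object@duration,
              length(object@times) / object@duration))
})

setMethod("show", "ToneSchedule", function(object) {
  cat(sprintf("ToneSchedule: %d freqs x %d reps at %.2f Hz (%.2f s)\n",
              object@nFreqs, object@nReps, object@rate, duration(object)))
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet (%s code): %d windows of %.0f ms, stride %.0f ms, %d unit(s), dim %d\n",
              object@codeKind, length(object@starts), object@length * 1e3,
              object@stride * 1e3, length(object@unitIds), ncol(object@vectors)))
})

setMethod("show", "NeighborTable", function(object) {
  cat(sprintf("NeighborTable: %d queries x k = %d neighbors (of %d candidates), exclusion %.0f ms\n",
              length(object@queryIdx), object@k, length(object@candIdx),
              object@exclusionHalfwidth * 1e3))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s code, %s windows): NCR = %.3f (r = %.4g)\n",
              object@codeKind, object@maskKind, object@ncr, object@corrSigned))
  cat(sprintf("  window %.0f ms, k = %d, lags {%s} ms, %d queries\n",
              object@windowLength * 1e3, object@k,
              paste(round(object@lags * 1e3), collapse = ", "),
              object@nQueries))
})

setMethod("show", "NullCalibration", function(object) {
  cat(sprintf("NullCalibration: %d Poisson trains, %d NCR samples, %gth percentile threshold = %.3f\n",
              object@nTrains, nrow(object@samples), object@percentile,
              object@threshold))
})

setMethod("show", "PairDecomposition", function(object) {
  cat(sprintf("PairDecomposition: normalized synergy = %.1f%% over %d valid bins\n",
              object@normalizedSynergy, object@nValidBins))
})

setMethod("show", "STRF", function(object) {
  ft <- object@features
  cat(sprintf("STRF: %d freqs x %d ms; BF = %s kHz, bandwidth = %.2f oct, max rate = %.1f sp/s\n",
              nrow(object@psth), ncol(object@psth),
              if (isTRUE(ft$bfReliable)) sprintf("%.2f", ft$bestFrequencyHz / 1e3) else "n/a",
              ft$bandwidthOct, ft$maxRate))
})

setMethod("show", "NCRParams", function(object) {
  cat(sprintf("NCRParams: window %.0f ms, strides %.0f/%.0f ms (cand/eval), k = %d, lags {%s} ms\n",
              object@windowLength * 1e3, object@candidateStride * 1e3,
              object@evalStride * 1e3, object@k,
              paste(round(object@lags * 1e3), collapse = ", ")))
})
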