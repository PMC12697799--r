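#' @include AllClasses.R
NULL

#' Total duration of a time-based object, in seconds
#'
#' @param x a \linkS4class{SpikeTrain}, \linkS4class{SweepPair},
#'   \linkS4class{Spectrogram} or \linkS4class{ToneSchedule}.
#' @return numeric scalar, seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Neural code reliability score
#'
#' NCR is \code{log10(|Corr|)} between the actual and decoded stimulus;
#' it is non-positive, and higher values mean a more reliable code.
#'
#' @param x a \linkS4class{DecodingResult}.
#' @return numeric scalar (\code{-Inf} flags a no-information result).
#' @export
setGeneric("ncr", function(x) standardGeneric("ncr"))

#' Channel center frequencies in Hz
#' @param x a \linkS4class{FrequencyAxis} or \linkS4class{Spectrogram}.
#' @return numeric vector of center frequencies (Hz), strictly increasing.
#' @export
setGeneric("frequencyCenters", function(x) standardGeneric("frequencyCenters"))

#' Time step of a gridded object, in seconds
#' @param x a \linkS4class{Spectrogram}, \linkS4class{SweepPair} or
#'   \linkS4class{DecodedStimulus}.
#' @return numeric scalar, seconds.
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' Spike times of a unit
#' @param x a \linkS4class{SpikeTrain}.
#' @return sorted numeric vector of spike times in seconds.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' Energy grid of a spectrogram
#' @param x a \linkS4class{Spectrogram}.
#' @return numeric matrix, frequency channels by time bins.
#' @export
setGeneric("energy", function(x) standardGeneric("energy"))

#' Per-dimension correlation profile of a decoding result
#'
#' \code{Corr[S;N](t)} is the correlation between actual and decoded
#' stimulus across frequency at each covered time bin;
#' \code{Corr[S;N](f)} is the correlation across covered time bins at
#' each frequency channel.
#'
#' @param x a \linkS4class{DecodingResult}.
#' @param dim \code{"time"} or \code{"frequency"}.
#' @return numeric vector with \code{NA} at bins that are uncovered or
#'   degenerate (zero variance).
#' @export
setGeneric("corrProfile", function(x, dim = c("time", "frequency"))
  standardGeneric("corrProfile"))

#' Calibrated null significance threshold
#' @param x a \linkS4class{NullCalibration}.
#' @return numeric scalar: the stated percentile of the pooled null NCR
#'   distribution.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' Normalized pair synergy, in percent
#' @param x a \linkS4class{PairDecomposition}.
#' @return numeric scalar in [-100, 100] (\code{NA} if no valid bins).
#' @export
setGeneric("normalizedSynergy", function(x) standardGeneric("normalizedSynergy"))

#' STRF feature record
#' @param x a \linkS4class{STRF}.
#' @return named list with \code{bestFrequencyHz}, \code{bandwidthOct},
#'   \code{maxRate}, \code{spontaneousRate}, \code{firstSpikeLatencyMs},
#'   \code{responseDurationMs} and \code{bfReliable}.
#' @export
setGeneric("strfFeatures", function(x) standardGeneric("strfFeatures"))
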