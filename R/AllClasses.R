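#' @import methods
#' @importFrom stats approx cor dnorm fft lm quantile rnorm rpois runif sd
#' @importFrom utils read.csv write.csv head
#' @useDynLib ncrtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Stimulus containers
## ---------------------------------------------------------------------------

#' Log-spaced frequency axis
#'
#' Channel center frequencies on a log2-uniform grid. The default analysis
#' axis has 45 channels covering 5.5 octaves from 2 to 90 kHz, matching the
#' tone set used to map spectrotemporal receptive fields.
#'
#' @slot centers numeric, strictly increasing center frequencies (Hz) with
#'   log2-uniform spacing.
#' @seealso [logFrequencyAxis()]
#' @export
setClass("FrequencyAxis", representation(centers = "numeric"),
  validity = function(object) {
    ctr <- object@centers
    if (length(ctr) < 2L) return("need at least two channels")
    if (any(!is.finite(ctr)) || any(ctr <= 0)) return("centers must be finite and positive")
    if (any(diff(ctr) <= 0)) return("centers must be strictly increasing")
    sp <- diff(log2(ctr))
    if (max(abs(sp - mean(sp))) > 1e-6 * mean(sp))
      return("centers must be log2-uniformly spaced")
    TRUE
  })

#' Pair of random-sweep voice trajectories
#'
#' The two instantaneous-frequency time series (in log2 Hz) of a random
#' double sweep: two pure-tone voices whose frequencies wander randomly
#' within a band, with all frequency-modulation power below a stated cutoff.
#'
#' @slot log2f numeric matrix, 2 x n: per-voice instantaneous log2(frequency/Hz).
#' @slot dt numeric, trajectory sampling step (s).
#' @slot bounds numeric length 2, band limits (Hz).
#' @slot speedCutoff numeric, FM low-pass cutoff (Hz).
#' @slot seed integer seed used to generate the pair.
#' @seealso [generateRDS()]
#' @export
setClass("SweepPair",
  representation(log2f = "matrix", dt = "numeric", bounds = "numeric",
                 speedCutoff = "numeric", seed = "integer"),
  validity = function(object) {
    if (nrow(object@log2f) != 2L) return("log2f must have exactly two rows (voices)")
    if (any(!is.finite(object@log2f))) return("trajectories must be finite")
    lb <- log2(object@bounds)
    if (any(object@log2f < lb[1] - 1e-9) || any(object@log2f > lb[2] + 1e-9))
      return("trajectories exceed the stated frequency bounds")
    if (object@dt <= 0) return("dt must be positive")
    TRUE
  })

#' Stimulus spectrogram
#'
#' The stimulus S as a non-negative energy grid, frequency channels by time
#' bins, on a log-spaced frequency axis.
#'
#' @slot energy numeric matrix, n_channels x n_time, non-negative.
#' @slot dt numeric, time step (s).
#' @slot axis a \linkS4class{FrequencyAxis}.
#' @seealso [renderSpectrogram()]
#' @export
setClass("Spectrogram",
  representation(energy = "matrix", dt = "numeric", axis = "FrequencyAxis"),
  validity = function(object) {
    if (any(!is.finite(object@energy))) return("energy must be finite")
    if (any(object@energy < 0)) return("energy must be non-negative")
    if (nrow(object@energy) != length(object@axis@centers))
      return("energy rows must match the frequency axis")
    if (object@dt <= 0) return("dt must be positive")
    TRUE
  })

#' Stimulus-complexity trace
#'
#' A per-time-bin description of how hard the two-voice stimulus is to
#' resolve: \code{proximity} (log2 octave distance between the voices),
#' \code{speed} (mean absolute FM speed, octaves/s) or \code{dissimilarity}
#' (sliding-window Pearson correlation of the two trajectories).
#'
#' @slot kind character, one of \code{"proximity"}, \code{"speed"},
#'   \code{"dissimilarity"}.
#' @slot values numeric, one value per trajectory sample (\code{NA} where
#'   undefined).
#' @slot valid logical, same length; \code{FALSE} flags edge/degenerate bins.
#' @slot dt numeric, trajectory step (s).
#' @slot params list of parameters used (window length, proximity floor).
#' @seealso [computeComplexity()]
#' @export
setClass("ComplexityTrace",
  representation(kind = "character", values = "numeric", valid = "logical",
                 dt = "numeric", params = "list"),
  validity = function(object) {
    if (!object@kind %in% c("proximity", "speed", "dissimilarity"))
      return("unknown complexity kind")
    if (length(object@values) != length(object@valid))
      return("values and valid must have equal length")
    TRUE
  })

#' Randomized pure-tone presentation schedule
#'
#' @slot events data.frame with columns \code{onset_s}, \code{freq_hz},
#'   \code{rep} (repetition index per frequency).
#' @slot rate numeric, presentation rate (Hz).
#' @slot nFreqs integer number of distinct frequencies.
#' @slot nReps integer repetitions per frequency.
#' @slot seed integer ordering seed.
#' @seealso [generateToneSchedule()]
#' @export
setClass("ToneSchedule",
  representation(events = "data.frame", rate = "numeric", nFreqs = "integer",
                 nReps = "integer", seed = "integer"),
  validity = function(object) {
    ev <- object@events
    if (!all(c("onset_s", "freq_hz", "rep") %in% names(ev)))
      return("events must have columns onset_s, freq_hz, rep")
    if (nrow(ev) != object@nFreqs * object@nReps)
      return("events must have nFreqs * nReps rows")
    if (any(diff(ev$onset_s) <= 0)) return("onsets must be strictly increasing")
    tab <- table(ev$freq_hz)
    if (any(tab != object@nReps))
      return("each frequency must appear exactly nReps times")
    TRUE
  })

## ---------------------------------------------------------------------------
## Spike containers
## ---------------------------------------------------------------------------

#' Spike train of one unit
#'
#' @slot times numeric, sorted spike times in seconds, within [0, duration].
#' @slot duration numeric, recording duration (s).
#' @slot unitId character label.
#' @seealso [simulatePoisson()], [simulateLNP()], [mergeUnits()]
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", duration = "numeric", unitId = "character"),
  validity = function(object) {
    tt <- object@times
    if (any(is.na(tt))) return("spike times must not contain NA")
    if (is.unsorted(tt)) return("spike times must be non-decreasing")
    if (length(tt) && (tt[1] < 0 || tt[length(tt)] > object@duration))
      return("spike times must lie within [0, duration]")
    if (object@duration <= 0) return("duration must be positive")
    TRUE
  })

#' Synthetic encoder specification
#'
#' Ground-truth model neurons: a homogeneous Poisson unit (null), or a
#' linear-nonlinear-Poisson (LNP) unit with a separable Gaussian
#' spectrotemporal filter, half-wave rectification, response latency,
#' spike-time jitter and an absolute refractory period.
#'
#' @slot kind \code{"poisson"} or \code{"lnp"}.
#' @slot baselineRate numeric, spontaneous rate (spikes/s).
#' @slot gain numeric, evoked spikes/s per unit filter drive.
#' @slot bf numeric, best frequency (Hz).
#' @slot bandwidth numeric, SD of the log2-frequency tuning (octaves).
#' @slot latency numeric, response latency (s).
#' @slot kernelWidth numeric, SD of the temporal integration kernel (s).
#' @slot jitter numeric, SD of Gaussian spike-time jitter (s).
#' @slot refractory numeric, absolute refractory period (s).
#' @slot seed integer seed.
#' @seealso [encoderSpec()], [simulateLNP()]
#' @export
setClass("EncoderSpec",
  representation(kind = "character", baselineRate = "numeric", gain = "numeric",
                 bf = "numeric", bandwidth = "numeric", latency = "numeric",
                 kernelWidth = "numeric", jitter = "numeric",
                 refractory = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("poisson", "lnp")) return("kind must be poisson or lnp")
    if (object@baselineRate < 0 || object@gain < 0) return("rates must be >= 0")
    if (object@latency < 0) return("latency must be >= 0")
    if (object@kind == "lnp" && (object@bandwidth <= 0 || object@bf <= 0))
      return("lnp units need positive bf and bandwidth")
    TRUE
  })

#' Hann-smoothed spike trace
#'
#' Spike counts on a fine grid convolved with a peak-normalized Hann taper;
#' the representation underlying the temporal code.
#'
#' @slot values numeric, smoothed trace (one value per bin, >= 0).
#' @slot binDt numeric, bin width (s), default 0.5 ms.
#' @slot duration numeric, trace duration (s).
#' @seealso [binAndSmooth()]
#' @export
setClass("SmoothedTrain",
  representation(values = "numeric", binDt = "numeric", duration = "numeric"),
  validity = function(object) {
    if (any(object@values < -1e-12)) return("smoothed trace must be non-negative")
    if (object@binDt <= 0) return("binDt must be positive")
    TRUE
  })

#' Per-window code vectors of one or several units
#'
#' Analysis windows tiled along the recording at a fixed stride. Each window
#' holds a code vector: for the temporal code, the concatenated
#' Hann-smoothed trace segments of all units; for the rate code, the
#' concatenated per-unit spike counts.
#'
#' @slot starts numeric, window start times (s).
#' @slot length numeric, window length (s), default 100 ms.
#' @slot stride numeric, window stride (s).
#' @slot codeKind \code{"temporal"} or \code{"rate"}.
#' @slot vectors numeric matrix, one row per window.
#' @slot counts integer matrix, raw per-unit spike counts per window
#'   (used to build silence/spiking/combinatorial masks).
#' @slot unitIds character, contributing units.
#' @slot duration numeric, recording duration (s).
#' @slot binDt numeric, temporal-code bin width (s).
#' @seealso [makeWindows()]
#' @export
setClass("WindowSet",
  representation(starts = "numeric", length = "numeric", stride = "numeric",
                 codeKind = "character", vectors = "matrix", counts = "matrix",
                 unitIds = "character", duration = "numeric", binDt = "numeric"),
  validity = function(object) {
    if (!object@codeKind %in% c("temporal", "rate"))
      return("codeKind must be temporal or rate")
    if (nrow(object@vectors) != length(object@starts))
      return("one code vector per window required")
    if (nrow(object@counts) != length(object@starts))
      return("one count row per window required")
    if (length(object@starts) &&
        (min(object@starts) < -1e-12 ||
         max(object@starts) + object@length > object@duration + 1e-9))
      return("windows must lie fully inside [0, duration]")
    if (any(object@counts < 0)) return("spike counts must be non-negative")
    TRUE
  })

#' Boolean analysis mask over windows
#'
#' @slot kind \code{"silence"}, \code{"spiking"} or \code{"combinatorial"}.
#' @slot flags logical, one per window.
#' @slot params list: role assignment for the combinatorial mask.
#' @seealso [makeMask()]
#' @export
setClass("WindowMask",
  representation(kind = "character", flags = "logical", params = "list"),
  validity = function(object) {
    if (!object@kind %in% c("silence", "spiking", "combinatorial"))
      return("unknown mask kind")
    TRUE
  })

## ---------------------------------------------------------------------------
## Decoder containers
## ---------------------------------------------------------------------------

#' k-nearest spiking-pattern table
#'
#' For each query window, the k candidate windows with the most similar
#' code vectors, candidates overlapping the query in time excluded.
#'
#' @slot queryIdx integer, indices of query windows in the window set.
#' @slot candIdx integer, indices of candidate windows in the window set.
#' @slot neighbors integer matrix, n_query x k, entries indexing
#'   \code{candIdx}.
#' @slot distances numeric matrix, n_query x k, non-decreasing per row.
#' @slot k integer.
#' @slot exclusionHalfwidth numeric (s): candidates with
#'   |start - query start| below this are excluded.
#' @slot tieSeed integer, seed resolving ties at the k-th distance.
#' @slot windowStarts numeric, start times of all windows in the set.
#' @slot windowLength numeric (s).
#' @seealso [findNeighbors()]
#' @export
setClass("NeighborTable",
  representation(queryIdx = "integer", candIdx = "integer",
                 neighbors = "matrix", distances = "matrix", k = "integer",
                 exclusionHalfwidth = "numeric", tieSeed = "integer",
                 windowStarts = "numeric", windowLength = "numeric"),
  validity = function(object) {
    if (ncol(object@neighbors) != object@k) return("neighbors must have k columns")
    if (nrow(object@neighbors) != length(object@queryIdx))
      return("one neighbor row per query required")
    if (any(apply(object@distances, 1L, is.unsorted)))
      return("distances must be non-decreasing within each row")
    TRUE
  })

#' Decoded (predicted) stimulus
#'
#' Pixelwise average of the stimulus segments behind the most similar
#' spiking patterns, overlaid at the requested stimulus-to-response lags.
#'
#' @slot predicted numeric matrix, same shape as the stimulus energy grid;
#'   \code{NA} where no window placement covers a column.
#' @slot coverage integer, per-time-bin count of contributing placements.
#' @slot lags numeric, lags averaged in the reconstruction (s).
#' @slot dt numeric, time step (s).
#' @slot axis a \linkS4class{FrequencyAxis}.
#' @seealso [reconstruct()]
#' @export
setClass("DecodedStimulus",
  representation(predicted = "matrix", coverage = "integer", lags = "numeric",
                 dt = "numeric", axis = "FrequencyAxis"),
  validity = function(object) {
    if (length(object@coverage) != ncol(object@predicted))
      return("coverage must have one entry per time bin")
    bad <- object@coverage == 0L & colSums(!is.na(object@predicted)) > 0L
    if (any(bad)) return("prediction defined on uncovered columns")
    TRUE
  })

#' Result of one decoding run
#'
#' @slot ncr numeric, log10 |Pearson correlation| between actual and decoded
#'   stimulus over covered pixels (<= 0; \code{-Inf} flags no information).
#' @slot corrSigned numeric, the signed correlation.
#' @slot corrT numeric, per-time-bin correlation across frequency
#'   (\code{NA} at uncovered/degenerate bins), one per stimulus column.
#' @slot corrF numeric, per-frequency correlation across covered time bins.
#' @slot codeKind \code{"temporal"} or \code{"rate"}.
#' @slot windowLength,candidateStride,evalStride numeric (s).
#' @slot k integer, neighbors averaged.
#' @slot lags numeric (s).
#' @slot maskKind \code{"full"}, \code{"silence"}, \code{"spiking"} or
#'   \code{"combinatorial"}.
#' @slot nQueries integer.
#' @slot dt numeric, stimulus time step (s).
#' @slot decoded the \linkS4class{DecodedStimulus}, or \code{NULL} when
#'   predictions are not kept.
#' @seealso [decode()], [score()]
#' @export
setClass("DecodingResult",
  representation(ncr = "numeric", corrSigned = "numeric", corrT = "numeric",
                 corrF = "numeric", codeKind = "character",
                 windowLength = "numeric", candidateStride = "numeric",
                 evalStride = "numeric", k = "integer", lags = "numeric",
                 maskKind = "character", nQueries = "integer", dt = "numeric",
                 decoded = "ANY"),
  validity = function(object) {
    if (is.finite(object@ncr) && object@ncr > 1e-12)
      return("ncr must be <= 0")
    if (is.finite(object@corrSigned) &&
        abs(abs(object@corrSigned) - 10^object@ncr) > 1e-8)
      return("|corrSigned| must equal 10^ncr")
    ok <- function(v) all(is.na(v) | (v >= -1 - 1e-9 & v <= 1 + 1e-9))
    if (!ok(object@corrT) || !ok(object@corrF))
      return("correlation profiles must lie in [-1, 1]")
    TRUE
  })

#' Poisson null calibration of the NCR significance threshold
#'
#' @slot samples data.frame with columns \code{code}, \code{rate},
#'   \code{unit}, \code{ncr} (one row per decoded null train and code).
#' @slot percentile numeric, percentile (0-100) defining the threshold.
#' @slot threshold numeric, that percentile of the pooled finite null NCRs.
#' @slot seed integer.
#' @slot nTrains integer.
#' @slot params list, full decoder parameter echo.
#' @seealso [calibrateNull()]
#' @export
setClass("NullCalibration",
  representation(samples = "data.frame", percentile = "numeric",
                 threshold = "numeric", seed = "integer", nTrains = "integer",
                 params = "list"),
  validity = function(object) {
    if (!all(c("code", "rate", "unit", "ncr") %in% names(object@samples)))
      return("samples must have columns code, rate, unit, ncr")
    if (object@percentile <= 0 || object@percentile >= 100)
      return("percentile must be in (0, 100)")
    TRUE
  })

## ---------------------------------------------------------------------------
## Pair decomposition containers
## ---------------------------------------------------------------------------

#' Per-frequency correlation profiles of a neuron pair
#'
#' Absolute per-frequency decoding profiles |Corr|(f) for each neuron alone
#' (c1, c2) and for the concatenated pair (c12), on a shared frequency axis.
#'
#' @slot c1,c2,c12 numeric in [0, 1], \code{NA} flags missing bins.
#' @slot axis a \linkS4class{FrequencyAxis}.
#' @seealso [pairProfiles()], [decomposePair()]
#' @export
setClass("PairProfiles",
  representation(c1 = "numeric", c2 = "numeric", c12 = "numeric",
                 axis = "FrequencyAxis"),
  validity = function(object) {
    n <- length(object@axis@centers)
    if (length(object@c1) != n || length(object@c2) != n || length(object@c12) != n)
      return("profiles must match the frequency axis length")
    rng <- function(v) all(is.na(v) | (v >= -1e-9 & v <= 1 + 1e-9))
    if (!rng(object@c1) || !rng(object@c2) || !rng(object@c12))
      return("profiles must lie in [0, 1]")
    TRUE
  })

#' Synergy/redundancy decomposition of a pair's decoding profiles
#'
#' Redundancy(f) = min(c1, c2)(f); Synergy(f) = c12(f) - max(c1, c2)(f),
#' so that c12 = Synergy + c1 + c2 - Redundancy bin-wise. The normalized
#' synergy divides each bin by max(c12, c1, c2)(f) and averages over valid
#' bins, in percent within [-100, 100].
#'
#' @slot synergyF,redundancyF numeric per-frequency profiles.
#' @slot normalizedSynergy numeric scalar, percent (\code{NA} if no valid bin).
#' @slot nValidBins integer, bins entering the normalized average.
#' @seealso [decomposePair()]
#' @export
setClass("PairDecomposition",
  representation(synergyF = "numeric", redundancyF = "numeric",
                 normalizedSynergy = "numeric", nValidBins = "integer"),
  validity = function(object) {
    if (length(object@synergyF) != length(object@redundancyF))
      return("profiles must have equal length")
    ns <- object@normalizedSynergy
    if (!is.na(ns) && (ns < -100 - 1e-9 || ns > 100 + 1e-9))
      return("normalized synergy must lie in [-100, 100]")
    TRUE
  })

## ---------------------------------------------------------------------------
## STRF containers
## ---------------------------------------------------------------------------

#' Spectrotemporal receptive field
#'
#' Pure-tone PSTH grid (1 ms bins, spikes/s), its 5x5 uniform-smoothed copy,
#' baseline statistics from the first 10 ms, the 6-SD significance mask and
#' the extracted feature record.
#'
#' @slot psth numeric matrix, n_freq x n_time, spikes/s.
#' @slot smoothed numeric matrix, same shape.
#' @slot binDt numeric, PSTH bin (s).
#' @slot axis a \linkS4class{FrequencyAxis}.
#' @slot baselineMean,baselineSd numeric, baseline statistics (spikes/s).
#' @slot mask logical matrix: smoothed > baselineMean + sdThreshold * baselineSd.
#' @slot sdThreshold numeric, significance criterion in baseline SDs.
#' @slot features list, see [strfFeatures()].
#' @seealso [buildSTRF()]
#' @export
setClass("STRF",
  representation(psth = "matrix", smoothed = "matrix", binDt = "numeric",
                 axis = "FrequencyAxis", baselineMean = "numeric",
                 baselineSd = "numeric", mask = "matrix",
                 sdThreshold = "numeric", features = "list"),
  validity = function(object) {
    if (any(object@psth < 0)) return("psth must be non-negative")
    if (!identical(dim(object@psth), dim(object@smoothed)) ||
        !identical(dim(object@psth), dim(object@mask)))
      return("psth, smoothed and mask must share dimensions")
    if (nrow(object@psth) != length(object@axis@centers))
      return("psth rows must match the frequency axis")
    TRUE
  })

#' Best-frequency-centered reliability profile
#'
#' A per-frequency reliability profile normalized by its maximum and
#' re-indexed by octave offset from the unit's best frequency. Offsets that
#' fall outside the frequency axis are \code{NA}.
#'
#' @slot offsets numeric, octave offsets from best frequency.
#' @slot values numeric, normalized profile (max 1 where defined).
#' @slot spacing numeric, channel spacing in octaves.
#' @seealso [bfCenteredProfile()], [averageBFProfiles()]
#' @export
setClass("BFProfile",
  representation(offsets = "numeric", values = "numeric", spacing = "numeric"),
  validity = function(object) {
    if (length(object@offsets) != length(object@values))
      return("offsets and values must have equal length")
    TRUE
  })

#' Decoder parameter bundle
#'
#' All tunable decoder parameters with their defaults: 100 ms windows,
#' 10 ms candidate stride, 50 ms evaluation stride, k = 100 neighbors,
#' reconstruction lags {-10, 0} ms, 0.5 ms temporal-code bins with a 9 ms
#' Hann taper.
#'
#' @slot windowLength numeric (s).
#' @slot candidateStride numeric (s), stride of the candidate window grid.
#' @slot evalStride numeric (s), stride of the query (evaluation) grid.
#' @slot k integer, neighbors averaged.
#' @slot lags numeric (s), stimulus offsets averaged in the reconstruction.
#' @slot binDt numeric (s), temporal-code bin width.
#' @slot hannLen numeric (s), Hann taper support.
#' @slot tieSeed integer, tie-resolution seed.
#' @slot exclusionHalfwidth numeric (s), overlap-exclusion halfwidth
#'   (defaults to the window length).
#' @slot keepPrediction logical, keep the predicted spectrogram in results.
#' @seealso [ncrParams()]
#' @export
setClass("NCRParams",
  representation(windowLength = "numeric", candidateStride = "numeric",
                 evalStride = "numeric", k = "integer", lags = "numeric",
                 binDt = "numeric", hannLen = "numeric", tieSeed = "integer",
                 exclusionHalfwidth = "numeric", keepPrediction = "logical"),
  validity = function(object) {
    if (object@windowLength <= 0 || object@candidateStride <= 0 ||
        object@evalStride <= 0 || object@binDt <= 0)
      return("window length, strides and binDt must be positive")
    if (object@k < 1L) return("k must be >= 1")
    if (!length(object@lags)) return("at least one lag required")
    TRUE
  })
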