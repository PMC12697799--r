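#' @include AllClasses.R engine.R
NULL

#' Bundle per-frequency pair profiles
#'
#' @param c1,c2 absolute per-frequency decoding profiles |Corr|(f) of each
#'   neuron alone, in [0, 1] (\code{NA} = missing bin).
#' @param c12 the joint (concatenated pair) profile.
#' @param axis shared \linkS4class{FrequencyAxis}.
#' @return a \linkS4class{PairProfiles}.
#' @export
pairProfiles <- function(c1, c2, c12, axis = logFrequencyAxis()) {
  new("PairProfiles", c1 = as.numeric(c1), c2 = as.numeric(c2),
      c12 = as.numeric(c12), axis = axis)
}

#' Decompose a pair's decoding profiles into synergy and redundancy
#'
#' Redundancy at frequency f is the smaller of the two individual
#' profiles, min(c1, c2)(f) -- the information obtainable from either
#' neuron alone. Synergy is what the joint profile adds beyond the better
#' neuron, c12(f) - max(c1, c2)(f), so that the identity
#' c12 = synergy + c1 + c2 - redundancy holds bin-wise by construction.
#' The normalized synergy divides each bin by max(c12, c1, c2)(f), averages
#' over valid bins and is expressed in percent: it reaches +100 when both
#' individual profiles are zero but the joint profile is positive, -100
#' when both individual profiles are positive but the joint one is zero,
#' and 0 when the joint profile equals the better individual profile.
#' Bins where the three-way maximum is zero (or any profile is missing)
#' are excluded from the average and counted out of \code{nValidBins}.
#'
#' @param profiles a \linkS4class{PairProfiles}.
#' @return a \linkS4class{PairDecomposition}; if no bin is valid, the
#'   normalized synergy is \code{NA} and \code{nValidBins} is 0.
#' @examples
#' p <- pairProfiles(rep(0, 45), rep(0, 45), rep(0.5, 45))
#' normalizedSynergy(decomposePair(p))
#' @export
decomposePair <- function(profiles) {
  stopifnot(is(profiles, "PairProfiles"))
  c1 <- profiles@c1; c2 <- profiles@c2; c12 <- profiles@c12
  redundancy <- pmin(c1, c2)
  synergy <- c12 - pmax(c1, c2)
  max3 <- pmax(c12, c1, c2)
  valid <- !is.na(c1) & !is.na(c2) & !is.na(c12) & max3 > 0
  ns <- if (any(valid)) mean(100 * synergy[valid] / max3[valid]) else NA_real_
  new("PairDecomposition", synergyF = synergy, redundancyF = redundancy,
      normalizedSynergy = ns, nValidBins = as.integer(sum(valid)))
}

#' Full pair analysis: single, joint and decomposed decoding
#'
#' Decodes each unit alone and the concatenated pair, then decomposes the
#' absolute per-frequency profiles. Restricted variants re-decode the pair
#' on masked windows only -- spikes-only, silence-only, or the
#' combinatorial code (one unit firing while the other is silent) -- while
#' the individual profiles always come from the unrestricted single-unit
#' decodes, so restricted synergy is measured relative to the whole spike
#' train. The combinatorial restriction is evaluated for both role
#' assignments and both results are returned.
#'
#' @param unit1,unit2 \linkS4class{SpikeTrain}s.
#' @param stimulus the presented \linkS4class{Spectrogram}.
#' @param codeKind \code{"temporal"} or \code{"rate"}.
#' @param params an \linkS4class{NCRParams}.
#' @param restriction \code{"none"}, \code{"spikes"}, \code{"silence"} or
#'   \code{"combinatorial"}.
#' @return a list with elements \code{single1}, \code{single2}
#'   (\linkS4class{DecodingResult}s) and, for non-combinatorial
#'   restrictions, \code{pair}, \code{profiles}
#'   (\linkS4class{PairProfiles}) and \code{decomposition}
#'   (\linkS4class{PairDecomposition}); the combinatorial restriction
#'   instead carries \code{combinations}, a list of two such
#'   pair/profiles/decomposition triplets, one per role assignment
#'   (\code{spiker1silent2}, \code{spiker2silent1}).
#' @export
pairAnalysis <- function(unit1, unit2, stimulus,
                         codeKind = c("temporal", "rate"),
                         params = ncrParams(),
                         restriction = c("none", "spikes", "silence",
                                         "combinatorial")) {
  codeKind <- match.arg(codeKind)
  restriction <- match.arg(restriction)
  stopifnot(is(unit1, "SpikeTrain"), is(unit2, "SpikeTrain"),
            is(stimulus, "Spectrogram"))
  s1 <- decode(unit1, stimulus, codeKind, params)
  s2 <- decode(unit2, stimulus, codeKind, params)
  pairUnits <- list(unit1, unit2)
  pairWindows <- makeWindows(pairUnits, codeKind,
                             length = params@windowLength,
                             stride = params@candidateStride,
                             binDt = params@binDt, hannLen = params@hannLen)
  runPair <- function(mask) {
    p12 <- decode(pairUnits, stimulus, codeKind, params, mask = mask)
    prof <- pairProfiles(abs(s1@corrF), abs(s2@corrF), abs(p12@corrF),
                         axis = stimulus@axis)
    list(pair = p12, profiles = prof, decomposition = decomposePair(prof))
  }
  if (restriction == "none") {
    out <- runPair(NULL)
  } else if (restriction %in% c("spikes", "silence")) {
    kind <- if (restriction == "spikes") "spiking" else "silence"
    out <- runPair(makeMask(pairWindows, kind))
  } else {
    m12 <- makeMask(pairWindows, "combinatorial",
                    roles = list(spiker = 1L, silent = 2L))
    m21 <- makeMask(pairWindows, "combinatorial",
                    roles = list(spiker = 2L, silent = 1L))
    if (!any(m12@flags) && !any(m21@flags))
      stop("empty restriction: no window has one unit firing while the other is silent")
    out <- list(combinations = list(spiker1silent2 = runPair(m12),
                                    spiker2silent1 = runPair(m21)))
  }
  c(list(single1 = s1, single2 = s2, codeKind = codeKind,
         restriction = restriction), out)
}
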