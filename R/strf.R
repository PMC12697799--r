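#' @include AllClasses.R stimulus.R
NULL

# 5x5 uniform smoothing with reflective edge padding
smooth5x5 <- function(m) {
  pad <- 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(pmin(3L:2L, nr), seq_len(nr), pmax(nr - 1L:2L, 1L))
  cidx <- c(pmin(3L:2L, nc), seq_len(nc), pmax(nc - 1L:2L, 1L))
  mp <- m[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in -pad:pad)
    for (dc in -pad:pad)
      out <- out + mp[seq_len(nr) + pad + dr, seq_len(nc) + pad + dc,
                      drop = FALSE]
  out / 25
}

#' Build a spectrotemporal receptive field from tone responses
#'
#' Constructs a post-stimulus time histogram per tone frequency (1 ms bins,
#' averaged over repetitions, in spikes/s), smooths it with a uniform 5x5
#' bin window (reflective edges), estimates baseline statistics from the
#' first 10 ms of the raw PSTH (whose SD carries the per-bin counting
#' noise the criterion must beat), and marks bins where the smoothed rate
#' exceeds the baseline mean plus \code{sdThreshold} baseline SDs
#' (default 6) as significant.
#' A silent baseline (SD 0) falls back to the Poisson SD of the baseline
#' rate floored at one expected spike, to keep the criterion defined.
#'
#' @param train a \linkS4class{SpikeTrain} recorded under the schedule.
#' @param schedule the \linkS4class{ToneSchedule} that was presented.
#' @param analysisWindow PSTH extent after each onset (s); defaults to the
#'   inter-onset interval and may not exceed it.
#' @param binDt PSTH bin (s), default 1 ms.
#' @param baselineLen baseline extent (s), default 10 ms.
#' @param sdThreshold significance criterion in baseline SDs.
#' @return an \linkS4class{STRF} with extracted features.
#' @export
buildSTRF <- function(train, schedule, analysisWindow = NULL, binDt = 1e-3,
                      baselineLen = 0.010, sdThreshold = 6) {
  stopifnot(is(train, "SpikeTrain"), is(schedule, "ToneSchedule"))
  ioi <- 1 / schedule@rate
  if (is.null(analysisWindow)) analysisWindow <- floor(ioi / binDt) * binDt
  if (analysisWindow > ioi + 1e-9)
    stop("'analysisWindow' may not exceed the inter-onset interval")
  nb <- round(analysisWindow / binDt)
  freqs <- sort(unique(schedule@events$freq_hz))
  axis <- new("FrequencyAxis", centers = freqs)
  counts <- matrix(0, length(freqs), nb)
  nev <- integer(length(freqs))
  tt <- train@times
  for (i in seq_len(nrow(schedule@events))) {
    on <- schedule@events$onset_s[i]
    fi <- match(schedule@events$freq_hz[i], freqs)
    nev[fi] <- nev[fi] + 1L
    lo <- findInterval(on - 1e-12, tt) + 1L
    hi <- findInterval(on + analysisWindow - 1e-12, tt)
    if (hi >= lo) {
      b <- floor((tt[lo:hi] - on) / binDt) + 1L
      b <- b[b >= 1L & b <= nb]
      counts[fi, ] <- counts[fi, ] + tabulate(b, nbins = nb)
    }
  }
  if (any(nev == 0L))
    stop(sprintf("no events for frequency %.0f Hz", freqs[which(nev == 0L)[1]]))
  psth <- counts / (nev * binDt)
  smoothed <- smooth5x5(psth)
  bcols <- seq_len(max(1L, round(baselineLen / binDt)))
  # baseline statistics from the raw 1 ms PSTH bins: their SD carries the
  # per-bin counting noise, which is the scale the 6-SD criterion must
  # beat; the smoothed grid is only the surface the contour is drawn on
  bvals <- psth[, bcols]
  bmean <- mean(bvals)
  bsd <- sd(as.vector(bvals))
  if (!is.finite(bsd) || bsd < 1e-12) {
    expCount <- max(bmean * binDt * schedule@nReps, 1)
    bsd <- sqrt(expCount) / (binDt * schedule@nReps)
  }
  mask <- smoothed > bmean + sdThreshold * bsd
  obj <- new("STRF", psth = psth, smoothed = smoothed, binDt = binDt,
             axis = axis, baselineMean = bmean, baselineSd = bsd,
             mask = mask, sdThreshold = sdThreshold, features = list())
  obj@features <- extractSTRFFeatures(obj)
  obj
}

#' Extract features from an STRF
#'
#' Best frequency is the frequency of the highest smoothed rate; bandwidth
#' is the summed frequency extent, in octaves, of the connected significant
#' channel runs (each run counts its channels times the channel spacing);
#' first-spike latency is the first time bin at which the smoothed PSTH at
#' best frequency exceeds the significance criterion, and response duration
#' the total significant time extent at best frequency (both are package
#' conventions for features the field names without formulas). With an
#' empty significance mask the tuning features are flagged unreliable and
#' the rates are still reported.
#'
#' @param strf an \linkS4class{STRF}.
#' @return named list: \code{bestFrequencyHz}, \code{bandwidthOct},
#'   \code{maxRate}, \code{spontaneousRate}, \code{firstSpikeLatencyMs},
#'   \code{responseDurationMs}, \code{bfReliable}.
#' @export
extractSTRFFeatures <- function(strf) {
  stopifnot(is(strf, "STRF"))
  sm <- strf@smoothed
  spacing <- axisSpacing(strf@axis)
  pk <- arrayInd(which.max(sm), dim(sm))
  bfIdx <- pk[1L]
  feats <- list(bestFrequencyHz = strf@axis@centers[bfIdx],
                maxRate = max(sm),
                spontaneousRate = strf@baselineMean)
  sigFreq <- rowSums(strf@mask) > 0L
  if (!any(sigFreq)) {
    feats$bandwidthOct <- 0
    feats$firstSpikeLatencyMs <- NA_real_
    feats$responseDurationMs <- NA_real_
    feats$bfReliable <- FALSE
    return(feats)
  }
  runs <- rle(sigFreq)
  feats$bandwidthOct <- sum(runs$lengths[runs$values]) * spacing
  bfSig <- which(strf@mask[bfIdx, ])
  if (length(bfSig)) {
    feats$firstSpikeLatencyMs <- (bfSig[1L] - 1L) * strf@binDt * 1e3
    feats$responseDurationMs <- length(bfSig) * strf@binDt * 1e3
  } else {
    feats$firstSpikeLatencyMs <- NA_real_
    feats$responseDurationMs <- NA_real_
  }
  feats$bfReliable <- TRUE
  feats
}

#' Partition a reliability profile by STRF tuning
#'
#' Mean reliability for the frequency channels below, within and above the
#' significant STRF range (bounded by the lowest and highest significant
#' frequency). Empty regions are \code{NA}, not zero.
#'
#' @param profile per-frequency reliability values on the STRF axis.
#' @param strf an \linkS4class{STRF} with a non-empty significance mask.
#' @return list with \code{below}, \code{within}, \code{above} (means over
#'   valid bins) and \code{n}, the per-region valid-bin counts.
#' @export
partitionByTuning <- function(profile, strf) {
  stopifnot(is(strf, "STRF"))
  nf <- length(strf@axis@centers)
  if (length(profile) != nf)
    stop("'profile' must be on the STRF frequency axis")
  sigFreq <- which(rowSums(strf@mask) > 0L)
  if (!length(sigFreq))
    stop("partition undefined: the significance mask is empty")
  lo <- min(sigFreq); hi <- max(sigFreq)
  region <- function(idx) {
    v <- profile[idx]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  idxBelow <- seq_len(lo - 1L)
  idxWithin <- lo:hi
  idxAbove <- if (hi < nf) (hi + 1L):nf else integer(0)
  list(below = region(idxBelow), within = region(idxWithin),
       above = region(idxAbove),
       n = c(below = sum(is.finite(profile[idxBelow])),
             within = sum(is.finite(profile[idxWithin])),
             above = sum(is.finite(profile[idxAbove]))))
}

#' Center a reliability profile on the best frequency
#'
#' Divides a per-frequency reliability profile by its maximum and
#' re-indexes it by octave offset from the unit's best frequency; offsets
#' falling outside the axis are \code{NA}.
#'
#' @param profile per-frequency reliability values on \code{axis}.
#' @param bf best frequency (Hz).
#' @param axis the \linkS4class{FrequencyAxis}.
#' @return a \linkS4class{BFProfile}; an all-zero or all-missing profile
#'   yields all-\code{NA} values (sentinel).
#' @export
bfCenteredProfile <- function(profile, bf, axis = logFrequencyAxis()) {
  nf <- length(axis@centers)
  if (length(profile) != nf) stop("'profile' must match the axis length")
  spacing <- axisSpacing(axis)
  bfIdx <- which.min(abs(log2(axis@centers) - log2(bf)))
  offIdx <- seq(-(nf - 1L), nf - 1L)
  mx <- suppressWarnings(max(profile, na.rm = TRUE))
  vals <- rep(NA_real_, length(offIdx))
  if (is.finite(mx) && mx > 0) {
    srcIdx <- bfIdx + offIdx
    inside <- srcIdx >= 1L & srcIdx <= nf
    vals[inside] <- profile[srcIdx[inside]] / mx
  }
  new("BFProfile", offsets = offIdx * spacing, values = vals,
      spacing = spacing)
}

#' Average best-frequency-centered profiles across units
#'
#' Stacks profiles on their common octave-offset grid and takes
#' missing-aware means per offset.
#'
#' @param profiles list of \linkS4class{BFProfile} with identical offset
#'   grids.
#' @return a \linkS4class{BFProfile} of per-offset means (\code{NA} where
#'   no profile is defined).
#' @export
averageBFProfiles <- function(profiles) {
  if (!length(profiles) || !all(vapply(profiles, is, TRUE, "BFProfile")))
    stop("'profiles' must be a non-empty list of BFProfile objects")
  off <- profiles[[1L]]@offsets
  for (p in profiles)
    if (length(p@offsets) != length(off) ||
        max(abs(p@offsets - off)) > 1e-9)
      stop("profiles must share the same offset grid")
  stack <- do.call(rbind, lapply(profiles, function(p) p@values))
  m <- colMeans(stack, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  new("BFProfile", offsets = off, values = m,
      spacing = profiles[[1L]]@spacing)
}
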