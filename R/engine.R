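#' @include AllClasses.R utils.R codes.R
NULL

#' Construct a decoder parameter bundle
#'
#' @param windowLength analysis window (s), default 100 ms.
#' @param candidateStride stride of the candidate window grid (s).
#' @param evalStride stride of the query (evaluation) grid (s); must be a
#'   multiple of \code{candidateStride}.
#' @param k neighbors averaged per query, default 100.
#' @param lags stimulus offsets (s) averaged in the reconstruction,
#'   default \{-10, 0\} ms (negative = stimulus precedes the spikes).
#' @param binDt,hannLen temporal-code smoothing parameters.
#' @param tieSeed seed resolving distance ties at the k-th neighbor.
#' @param exclusionHalfwidth overlap-exclusion halfwidth (s); defaults to
#'   the window length so no candidate overlaps its query.
#' @param keepPrediction keep the predicted spectrogram in the result.
#' @return an \linkS4class{NCRParams}.
#' @examples
#' ncrParams(k = 50, evalStride = 0.1)
#' @export
ncrParams <- function(windowLength = 0.1, candidateStride = 0.01,
                      evalStride = 0.05, k = 100L, lags = c(-0.01, 0),
                      binDt = 5e-4, hannLen = 9e-3, tieSeed = 1L,
                      exclusionHalfwidth = NULL, keepPrediction = TRUE) {
  if (is.null(exclusionHalfwidth)) exclusionHalfwidth <- windowLength
  r <- evalStride / candidateStride
  if (abs(r - round(r)) > 1e-9)
    stop("'evalStride' must be an integer multiple of 'candidateStride'")
  new("NCRParams", windowLength = windowLength,
      candidateStride = candidateStride, evalStride = evalStride,
      k = as.integer(k), lags = lags, binDt = binDt, hannLen = hannLen,
      tieSeed = as.integer(tieSeed),
      exclusionHalfwidth = exclusionHalfwidth,
      keepPrediction = isTRUE(keepPrediction))
}

#' Find the k most similar non-overlapping spiking patterns
#'
#' For each query window, the k candidate windows with the smallest code
#' distance, excluding candidates whose window overlaps the query in time
#' (|start difference| < \code{exclusionHalfwidth}). Ties at the k-th
#' distance are resolved by seeded uniform sampling among the tied
#' candidates, so results are reproducible under \code{tieSeed}.
#'
#' @param windows a \linkS4class{WindowSet}.
#' @param k neighbors per query.
#' @param exclusionHalfwidth exclusion halfwidth (s); default the window
#'   length.
#' @param tieSeed integer seed.
#' @param queryIdx indices of query windows (default: all windows).
#' @param candIdx indices of candidate windows (default: all windows).
#' @return a \linkS4class{NeighborTable}.
#' @export
findNeighbors <- function(windows, k = 100L,
                          exclusionHalfwidth = windows@length,
                          tieSeed = 1L, queryIdx = NULL, candIdx = NULL) {
  stopifnot(is(windows, "WindowSet"))
  k <- as.integer(k)
  n <- length(windows@starts)
  if (is.null(queryIdx)) queryIdx <- seq_len(n)
  if (is.null(candIdx)) candIdx <- seq_len(n)
  queryIdx <- as.integer(queryIdx)
  candIdx <- as.integer(candIdx)
  if (!length(queryIdx)) stop("no query windows selected")
  if (length(candIdx) < k)
    stop(sprintf("neighbor capacity: only %d candidate windows for k = %d; reduce k or the stride",
                 length(candIdx), k))
  res <- cpp_topk_neighbors(windows@vectors[queryIdx, , drop = FALSE],
                            windows@vectors[candIdx, , drop = FALSE],
                            windows@starts[queryIdx],
                            windows@starts[candIdx],
                            exclusionHalfwidth, k, as.integer(tieSeed))
  new("NeighborTable", queryIdx = queryIdx, candIdx = candIdx,
      neighbors = res$idx, distances = res$dist, k = k,
      exclusionHalfwidth = exclusionHalfwidth,
      tieSeed = as.integer(tieSeed), windowStarts = windows@starts,
      windowLength = windows@length)
}

#' Reconstruct the stimulus from a neighbor table
#'
#' For each query window at time t, the k neighbor stimulus segments are
#' averaged at each lag (the segment behind candidate window w at lag g
#' starts at w + g) and the per-query prediction is placed at t + g;
#' overlapping placements and lags are averaged pixelwise, weights summing
#' to one per covered pixel. Segments or placements extending beyond the
#' stimulus are dropped.
#'
#' @param neighbors a \linkS4class{NeighborTable}.
#' @param stimulus the actual \linkS4class{Spectrogram}.
#' @param lags stimulus offsets (s), default \{-10, 0\} ms.
#' @return a \linkS4class{DecodedStimulus}.
#' @export
reconstruct <- function(neighbors, stimulus, lags = c(-0.01, 0)) {
  stopifnot(is(neighbors, "NeighborTable"), is(stimulus, "Spectrogram"))
  if (!length(lags)) stop("at least one lag is required")
  dt <- stimulus@dt
  candCol <- asGridUnits(neighbors@windowStarts[neighbors@candIdx], dt,
                         "window starts")
  queryCol <- asGridUnits(neighbors@windowStarts[neighbors@queryIdx], dt,
                          "window starts")
  lagCol <- asGridUnits(lags, dt, "lags")
  lcols <- max(1L, as.integer(round(neighbors@windowLength / dt)))
  res <- cpp_reconstruct(stimulus@energy, neighbors@neighbors, candCol,
                         queryCol, lagCol, lcols)
  cnt <- as.integer(round(res$count))
  pred <- res$sum
  covered <- cnt > 0L
  pred[, covered] <- sweep(pred[, covered, drop = FALSE], 2L,
                           cnt[covered], "/")
  pred[, !covered] <- NA_real_
  new("DecodedStimulus", predicted = pred, coverage = cnt, lags = lags,
      dt = dt, axis = stimulus@axis)
}

#' Score a reconstruction against the actual stimulus
#'
#' The signed Pearson correlation between actual and predicted stimulus
#' over all covered pixels (both flattened), its NCR = log10 |Corr|, and
#' the per-time-bin (across frequency) and per-frequency (across covered
#' time) correlation profiles. A constant prediction carries no
#' information: the correlation is undefined and the result is flagged
#' with \code{corrSigned = NA} and \code{ncr = -Inf}.
#'
#' @param actual the \linkS4class{Spectrogram} that was presented.
#' @param decoded a \linkS4class{DecodedStimulus}.
#' @param codeKind,maskKind,params metadata recorded in the result (filled
#'   in automatically by [decode()]).
#' @param nQueries number of query windows (metadata).
#' @return a \linkS4class{DecodingResult}.
#' @export
score <- function(actual, decoded, codeKind = "unspecified",
                  maskKind = "full", params = ncrParams(),
                  nQueries = NA_integer_) {
  stopifnot(is(actual, "Spectrogram"), is(decoded, "DecodedStimulus"))
  covered <- which(decoded@coverage > 0L)
  if (!length(covered)) stop("empty coverage: nothing was reconstructed")
  A <- actual@energy
  P <- decoded@predicted
  av <- as.vector(A[, covered])
  pv <- as.vector(P[, covered])
  if (sd(av) < 1e-14 || sd(pv) < 1e-14) {
    corrSigned <- NA_real_
    ncrVal <- -Inf
  } else {
    corrSigned <- cor(av, pv)
    ncrVal <- if (abs(corrSigned) < 1e-300) -Inf else log10(abs(corrSigned))
  }
  prof <- cpp_corr_profiles(A, P, covered - 1L)
  new("DecodingResult", ncr = ncrVal, corrSigned = corrSigned,
      corrT = as.numeric(prof$corrT), corrF = as.numeric(prof$corrF),
      codeKind = codeKind, windowLength = params@windowLength,
      candidateStride = params@candidateStride,
      evalStride = params@evalStride, k = params@k, lags = decoded@lags,
      maskKind = maskKind, nQueries = as.integer(nQueries),
      dt = actual@dt,
      decoded = if (params@keepPrediction) decoded else NULL)
}

# windows + neighbor table for a decode run; mask restricts both the query
# and the candidate pools
prepareNeighbors <- function(units, stimulus, codeKind, params, mask = NULL) {
  windows <- makeWindows(units, codeKind, length = params@windowLength,
                         stride = params@candidateStride,
                         binDt = params@binDt, hannLen = params@hannLen)
  starts <- windows@starts
  r <- starts / params@evalStride
  onEvalGrid <- which(abs(r - round(r)) < 1e-9)
  if (is.null(mask)) {
    queryIdx <- onEvalGrid
    candIdx <- seq_along(starts)
    maskKind <- "full"
  } else {
    stopifnot(is(mask, "WindowMask"))
    if (length(mask@flags) != length(starts))
      stop("mask length does not match the window set")
    flagged <- which(mask@flags)
    if (!length(flagged))
      stop(sprintf("empty restriction: no window satisfies the '%s' mask",
                   mask@kind))
    queryIdx <- intersect(onEvalGrid, flagged)
    if (!length(queryIdx))
      stop(sprintf("empty restriction: no '%s' window on the evaluation grid",
                   mask@kind))
    candIdx <- flagged
    maskKind <- mask@kind
  }
  if (length(candIdx) < params@k)
    stop(sprintf("neighbor capacity: %d candidate windows under mask '%s' for k = %d; reduce k or the stride",
                 length(candIdx), maskKind, params@k))
  nb <- findNeighbors(windows, k = params@k,
                      exclusionHalfwidth = params@exclusionHalfwidth,
                      tieSeed = params@tieSeed, queryIdx = queryIdx,
                      candIdx = candIdx)
  list(windows = windows, neighbors = nb, maskKind = maskKind)
}

#' Decode a stimulus from spike trains and score the reconstruction
#'
#' The full pipeline: build per-window code vectors, find the k most
#' similar non-overlapping spiking patterns for every query window,
#' average the stimulus segments behind them at the requested lags, and
#' score the reconstruction by NCR. With a \linkS4class{WindowMask}, both
#' the query and the candidate pools are restricted to flagged windows
#' (silence-only, spikes-only or combinatorial decoding).
#'
#' @param units a \linkS4class{SpikeTrain} or list thereof (a list decodes
#'   the group through concatenated code vectors).
#' @param stimulus the presented \linkS4class{Spectrogram}.
#' @param codeKind \code{"temporal"} or \code{"rate"}.
#' @param params an \linkS4class{NCRParams}.
#' @param mask optional \linkS4class{WindowMask} built by [makeMask()] on
#'   windows with the same length and stride.
#' @return a \linkS4class{DecodingResult}.
#' @examples
#' sw <- generateRDS(duration = 20, seed = 1)
#' sp <- renderSpectrogram(sw, dt = 0.005)
#' un <- simulateLNP(encoderSpec(bf = 16000, gain = 100, seed = 2), sp)
#' res <- decode(un, sp, "temporal", ncrParams(k = 30))
#' ncr(res)
#' @export
decode <- function(units, stimulus, codeKind = c("temporal", "rate"),
                   params = ncrParams(), mask = NULL) {
  codeKind <- match.arg(codeKind)
  stopifnot(is(stimulus, "Spectrogram"))
  prep <- prepareNeighbors(units, stimulus, codeKind, params, mask)
  dec <- reconstruct(prep$neighbors, stimulus, lags = params@lags)
  score(stimulus, dec, codeKind = codeKind, maskKind = prep$maskKind,
        params = params, nQueries = length(prep$neighbors@queryIdx))
}

#' Scan stimulus-to-response delays
#'
#' Decodes at each single delay d (the stimulus segment preceding the
#' spiking pattern by d seconds, i.e. lag -d) and reports the delay
#' maximizing NCR; ties go to the smallest delay. The neighbor search is
#' delay-independent and is computed once.
#'
#' @param units,stimulus,codeKind,params,mask as in [decode()].
#' @param delays non-empty grid of delays (s), >= 0.
#' @return list with \code{table} (data.frame \code{delay}, \code{ncr}) and
#'   \code{bestDelay}.
#' @export
scanLags <- function(units, stimulus, codeKind = c("temporal", "rate"),
                     delays = seq(0, 0.05, by = 0.005),
                     params = ncrParams(), mask = NULL) {
  codeKind <- match.arg(codeKind)
  if (!length(delays)) stop("'delays' must be a non-empty grid")
  prep <- prepareNeighbors(units, stimulus, codeKind, params, mask)
  ncrs <- vapply(delays, function(d) {
    dec <- reconstruct(prep$neighbors, stimulus, lags = -d)
    score(stimulus, dec, codeKind = codeKind, maskKind = prep$maskKind,
          params = params, nQueries = length(prep$neighbors@queryIdx))@ncr
  }, numeric(1))
  best <- delays[which(ncrs >= max(ncrs) - 1e-12)]
  list(table = data.frame(delay = delays, ncr = ncrs),
       bestDelay = min(best))
}

#' Scan analysis window sizes
#'
#' One decode per window size; the default grid brackets the sizes at
#' which NCR typically peaks (12-200 ms depending on code and stage).
#'
#' @param units,stimulus,codeKind,params,mask as in [decode()].
#' @param sizes window lengths (s), positive and at most the stimulus
#'   duration.
#' @return data.frame with \code{size} and \code{ncr}.
#' @export
scanWindowSizes <- function(units, stimulus,
                            codeKind = c("temporal", "rate"),
                            sizes = c(0.012, 0.024, 0.048, 0.1, 0.2),
                            params = ncrParams(), mask = NULL) {
  codeKind <- match.arg(codeKind)
  if (!length(sizes)) stop("'sizes' must be a non-empty grid")
  if (any(sizes <= 0) || any(sizes > duration(stimulus)))
    stop("'sizes' must be positive and at most the stimulus duration")
  ncrs <- vapply(sizes, function(sz) {
    p <- ncrParams(windowLength = sz,
                   candidateStride = params@candidateStride,
                   evalStride = params@evalStride, k = params@k,
                   lags = params@lags, binDt = params@binDt,
                   hannLen = params@hannLen, tieSeed = params@tieSeed,
                   keepPrediction = FALSE)
    decode(units, stimulus, codeKind, p, mask)@ncr
  }, numeric(1))
  data.frame(size = sizes, ncr = ncrs)
}

#' Calibrate the NCR significance threshold from Poisson null trains
#'
#' Simulates homogeneous Poisson spike trains at a spread of rates,
#' decodes each under the temporal and rate codes against the stimulus,
#' pools the null NCR samples and takes an upper percentile as the
#' significance threshold. The null NCR does not depend on the firing
#' rate, so one pooled threshold serves both codes.
#'
#' @param stimulus the \linkS4class{Spectrogram} to decode against.
#' @param rates firing rates (spikes/s); default a log-spaced grid over
#'   2-40 spikes/s with one rate per train.
#' @param nTrains number of null trains (>= 20 recommended for a stable
#'   percentile).
#' @param percentile upper percentile (0-100) defining the threshold.
#' @param params an \linkS4class{NCRParams}; predictions are not kept.
#' @param seed integer seed; per-train seeds are derived from it.
#' @param codes code kinds to pool, default both.
#' @return a \linkS4class{NullCalibration}.
#' @export
calibrateNull <- function(stimulus, rates = NULL, nTrains = 100L,
                          percentile = 95, params = ncrParams(),
                          seed = 1L, codes = c("temporal", "rate")) {
  stopifnot(is(stimulus, "Spectrogram"))
  nTrains <- as.integer(nTrains)
  if (is.na(nTrains) || nTrains < 1L)
    stop("'nTrains' must be a positive integer")
  if (nTrains < 20L)
    warning("fewer than 20 null trains gives an unstable percentile")
  if (any(!codes %in% c("temporal", "rate"))) stop("unknown code kind")
  if (is.null(rates))
    rates <- exp(seq(log(2), log(40), length.out = nTrains))
  if (any(rates <= 0)) stop("'rates' must be positive")
  rates <- rep_len(rates, nTrains)
  params@keepPrediction <- FALSE
  dur <- duration(stimulus)
  rows <- vector("list", nTrains * length(codes))
  ri <- 0L
  for (i in seq_len(nTrains)) {
    train <- simulatePoisson(rates[i], dur, seed = deriveSeed(seed, i),
                             unitId = sprintf("null%03d", i))
    for (cd in codes) {
      res <- tryCatch(decode(train, stimulus, cd, params),
                      error = function(e)
                        stop(sprintf("null train %d (rate %.2f sp/s): %s",
                                     i, rates[i], conditionMessage(e)),
                             call. = FALSE))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(code = cd, rate = rates[i], unit = i,
                               ncr = res@ncr)
    }
  }
  samples <- do.call(rbind, rows)
  finite <- samples$ncr[is.finite(samples$ncr)]
  if (!length(finite)) stop("no finite null NCR samples")
  thr <- as.numeric(quantile(finite, percentile / 100, type = 7))
  new("NullCalibration", samples = samples, percentile = percentile,
      threshold = thr, seed = as.integer(seed), nTrains = nTrains,
      params = list(windowLength = params@windowLength,
                    candidateStride = params@candidateStride,
                    evalStride = params@evalStride, k = params@k,
                    lags = params@lags, binDt = params@binDt,
                    hannLen = params@hannLen, tieSeed = params@tieSeed))
}
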