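#' @include AllClasses.R utils.R
NULL

# peak-normalized Hann taper of total support hannLen at bin width binDt;
# 9 ms at 0.5 ms bins gives the 19-tap symmetric taper
hannTaper <- function(binDt, hannLen) {
  m <- round(hannLen / binDt)
  if (abs(hannLen / binDt - m) > 1e-6)
    stop("'hannLen' must be an integer multiple of 'binDt'")
  if (m %% 2L != 0L)
    stop("'hannLen' must discretize to an odd number of taps (even multiple of binDt)")
  ntaps <- m + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(ntaps - 1L)) / (ntaps - 1L)))
  w / max(w)
}

#' Bin and Hann-smooth a spike train
#'
#' Spike counts on a fine grid (default 0.5 ms) convolved with a
#' peak-normalized Hann taper of total support \code{hannLen} (default
#' 9 ms), the representation on which the temporal code's Euclidean
#' distance operates. A single spike yields a unit-height Hann bump.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param binDt bin width (s).
#' @param hannLen taper support (s); must discretize to an odd tap count.
#' @return a \linkS4class{SmoothedTrain} of the same duration.
#' @examples
#' tr <- new("SpikeTrain", times = 0.05, duration = 0.2, unitId = "u")
#' sm <- binAndSmooth(tr)
#' max(sm@values)
#' @export
binAndSmooth <- function(train, binDt = 5e-4, hannLen = 9e-3) {
  stopifnot(is(train, "SpikeTrain"))
  assertScalar(binDt, "binDt", positive = TRUE)
  w <- hannTaper(binDt, hannLen)
  h <- (length(w) - 1L) %/% 2L
  nb <- max(1L, round(train@duration / binDt))
  counts <- tabulate(pmin(floor(train@times / binDt) + 1L, nb), nbins = nb)
  padded <- c(rep(0, h), counts, rep(0, h))
  sm <- stats::filter(padded, w, method = "convolution", sides = 2)
  vals <- as.numeric(sm[(h + 1L):(h + nb)])
  vals[vals < 0] <- 0
  new("SmoothedTrain", values = vals, binDt = binDt,
      duration = train@duration)
}

#' Build per-window code vectors for one or several units
#'
#' Windows tile the recording at \code{stride}; each window's code vector
#' is, for the temporal code, the concatenated Hann-smoothed trace segments
#' of all units and, for the rate code, the concatenated per-unit spike
#' counts. Group decoding uses exactly these concatenated vectors.
#'
#' @param units a \linkS4class{SpikeTrain} or list thereof (equal durations).
#' @param codeKind \code{"temporal"} or \code{"rate"}.
#' @param length window length (s), default 100 ms.
#' @param stride window stride (s), default 10 ms.
#' @param binDt,hannLen temporal-code smoothing parameters.
#' @return a \linkS4class{WindowSet}.
#' @examples
#' tr <- simulatePoisson(10, 1, seed = 1)
#' w <- makeWindows(tr, "rate", length = 0.1, stride = 0.01)
#' length(w@starts)
#' @export
makeWindows <- function(units, codeKind = c("temporal", "rate"),
                        length = 0.1, stride = 0.01, binDt = 5e-4,
                        hannLen = 9e-3) {
  if (is(units, "SpikeTrain")) units <- list(units)
  if (!base::length(units) || !all(vapply(units, is, TRUE, "SpikeTrain")))
    stop("'units' must be a SpikeTrain or non-empty list of SpikeTrain")
  codeKind <- match.arg(codeKind)
  assertScalar(stride, "stride", positive = TRUE)
  assertScalar(length, "length", positive = TRUE)
  durs <- vapply(units, duration, numeric(1))
  if (max(durs) - min(durs) > 1e-9)
    stop("all units must share the same duration")
  dur <- durs[1]
  if (length > dur) stop("'length' exceeds the recording duration")
  nwin <- floor((dur - length) / stride + 1e-9) + 1L
  starts <- (seq_len(nwin) - 1L) * stride
  ## raw per-unit spike counts per window (half-open [s, s + length))
  counts <- vapply(units, function(u) {
    tt <- u@times
    findInterval(starts + length - 1e-12, tt) -
      findInterval(starts - 1e-12, tt)
  }, integer(nwin))
  counts <- matrix(as.integer(counts), nrow = nwin)
  if (codeKind == "rate") {
    vectors <- matrix(as.numeric(counts), nrow = nwin)
  } else {
    lbins <- round(length / binDt)
    startBin <- asGridUnits(starts, binDt, "window starts")
    segs <- lapply(units, function(u) {
      tr <- binAndSmooth(u, binDt = binDt, hannLen = hannLen)@values
      idx <- outer(startBin, seq_len(lbins) - 1L, "+") + 1L
      matrix(tr[idx], nrow = nwin)
    })
    vectors <- do.call(cbind, segs)
  }
  ids <- vapply(units, function(u) u@unitId, character(1))
  new("WindowSet", starts = starts, length = length, stride = stride,
      codeKind = codeKind, vectors = vectors, counts = counts,
      unitIds = ids, duration = dur, binDt = binDt)
}

#' Distance between two code vectors
#'
#' The Euclidean norm of the difference: for temporal vectors, the
#' Euclidean distance on Hann-smoothed spike traces; for rate vectors, the
#' Euclidean distance on per-unit spike counts (for a single unit the
#' absolute count difference).
#'
#' @param v1,v2 numeric code vectors of equal length and kind.
#' @return non-negative scalar.
#' @examples
#' codeDistance(c(5), c(2))
#' @export
codeDistance <- function(v1, v2) {
  if (base::length(v1) != base::length(v2))
    stop("code vectors must have equal dimensionality")
  sqrt(sum((v1 - v2)^2))
}

#' Build a silence / spiking / combinatorial window mask
#'
#' \code{silence} flags windows with zero spikes in every unit of the set;
#' \code{spiking} flags windows with at least one spike in any unit (the
#' two partition all windows); \code{combinatorial}, defined for exactly
#' two units, flags windows where the spiker unit fires and the silent
#' unit does not.
#'
#' @param windows a \linkS4class{WindowSet}.
#' @param kind mask kind.
#' @param roles for \code{combinatorial}: list or vector with elements
#'   \code{spiker} and \code{silent} giving unit indices (or ids) in the
#'   window set.
#' @return a \linkS4class{WindowMask}.
#' @export
makeMask <- function(windows, kind = c("silence", "spiking", "combinatorial"),
                     roles = list(spiker = 1L, silent = 2L)) {
  stopifnot(is(windows, "WindowSet"))
  kind <- match.arg(kind)
  cnt <- windows@counts
  if (kind == "silence") {
    flags <- rowSums(cnt) == 0L
    params <- list()
  } else if (kind == "spiking") {
    flags <- rowSums(cnt) > 0L
    params <- list()
  } else {
    if (ncol(cnt) != 2L)
      stop("combinatorial masks are defined only for exactly two units")
    resolve <- function(r) {
      if (is.character(r)) r <- match(r, windows@unitIds)
      r <- as.integer(r)
      if (is.na(r) || r < 1L || r > 2L) stop("invalid unit role assignment")
      r
    }
    sp <- resolve(roles$spiker)
    si <- resolve(roles$silent)
    if (sp == si) stop("spiker and silent roles must name different units")
    flags <- cnt[, sp] >= 1L & cnt[, si] == 0L
    params <- list(spiker = sp, silent = si)
  }
  new("WindowMask", kind = kind, flags = as.logical(flags), params = params)
}
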