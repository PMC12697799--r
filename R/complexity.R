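#' @include AllClasses.R utils.R
NULL

#' Stimulus-complexity traces of a sweep pair
#'
#' Three per-time-bin descriptions of how demanding the two-voice stimulus
#' is to resolve:
#' \describe{
#'   \item{proximity}{log2 of the absolute octave distance between the two
#'     voices (a log-distance: smaller values mean closer voices). Distances
#'     below \code{floor} octaves are floored before taking the log to
#'     avoid \code{-Inf}; the floor is recorded in \code{params}.}
#'   \item{speed}{mean of the two absolute FM speeds |d log2 f / dt|,
#'     in octaves/s.}
#'   \item{dissimilarity}{Pearson correlation of the two trajectories over
#'     a sliding window centered on each bin, in [-1, 1]; highly negative
#'     values flag strongly opposite voice motion. Edge bins and
#'     zero-variance windows are \code{NA}.}
#' }
#'
#' @param sweeps a \linkS4class{SweepPair}.
#' @param kind \code{"proximity"}, \code{"speed"} or \code{"dissimilarity"}.
#' @param window sliding-window length (s); required for dissimilarity
#'   (default 100 ms, matching the decoder analysis window).
#' @param proximityFloor proximity floor in octaves.
#' @return a \linkS4class{ComplexityTrace} at trajectory resolution.
#' @examples
#' sw <- generateRDS(duration = 5, seed = 1)
#' tr <- computeComplexity(sw, "speed")
#' mean(tr@values)
#' @export
computeComplexity <- function(sweeps, kind = c("proximity", "speed",
                                               "dissimilarity"),
                              window = 0.1, proximityFloor = 1e-3) {
  stopifnot(is(sweeps, "SweepPair"))
  kind <- match.arg(kind)
  l1 <- sweeps@log2f[1L, ]
  l2 <- sweeps@log2f[2L, ]
  n <- length(l1)
  dt <- sweeps@dt
  if (kind == "proximity") {
    vals <- log2(pmax(abs(l1 - l2), proximityFloor))
    return(new("ComplexityTrace", kind = kind, values = vals,
               valid = rep(TRUE, n), dt = dt,
               params = list(floorOct = proximityFloor)))
  }
  if (kind == "speed") {
    sp <- function(l) {
      d <- abs(diff(l)) / dt
      c(d, d[length(d)])              # repeat the last difference
    }
    vals <- (sp(l1) + sp(l2)) / 2
    return(new("ComplexityTrace", kind = kind, values = vals,
               valid = rep(TRUE, n), dt = dt, params = list()))
  }
  ## dissimilarity: centered sliding-window Pearson correlation
  if (is.null(window) || !is.finite(window) || window <= 0)
    stop("dissimilarity requires a positive 'window' (s)")
  half <- floor((window / dt) / 2)
  w <- 2L * as.integer(half) + 1L
  if (w > n) stop("'window' exceeds the trajectory duration")
  rs <- function(x) {                 # rolling sum over w centered bins
    cs <- cumsum(c(0, x))
    cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  }
  # center globally so constant trajectories cancel exactly and the
  # rolling-variance cancellation error stays at the variance scale
  l1 <- l1 - mean(l1)
  l2 <- l2 - mean(l2)
  s1 <- rs(l1); s2 <- rs(l2)
  s11 <- rs(l1 * l1); s22 <- rs(l2 * l2); s12 <- rs(l1 * l2)
  cov <- s12 - s1 * s2 / w
  v1 <- pmax(s11 - s1^2 / w, 0)
  v2 <- pmax(s22 - s2^2 / w, 0)
  den <- sqrt(v1 * v2)
  core <- ifelse(den > 1e-12 * w, cov / den, NA_real_)
  core <- pmin(pmax(core, -1), 1)
  vals <- rep(NA_real_, n)
  vals[(half + 1L):(n - half)] <- core
  new("ComplexityTrace", kind = kind, values = vals, valid = !is.na(vals),
      dt = dt, params = list(windowS = window))
}

#' Correlate a reliability time course with a complexity trace
#'
#' Pearson correlation, across time, between a per-time-bin reliability
#' measurement (|Corr|(t) from a decoding result, or any aligned series)
#' and a stimulus-complexity trace. The complexity trace is block-averaged
#' onto the reliability time grid before correlating.
#'
#' @param x a \linkS4class{DecodingResult} (its |Corr(t)| profile is used),
#'   or a numeric series.
#' @param trace a \linkS4class{ComplexityTrace}.
#' @param times for a numeric \code{x}, the start time (s) of each bin;
#'   bins are assumed contiguous with the median spacing.
#' @param minBins minimum overlapping valid bins required.
#' @return list with \code{r} (Pearson correlation; \code{NA} sentinel when
#'   either series is constant over the valid bins) and \code{n} (bins used).
#' @export
reliabilityComplexityCorrelation <- function(x, trace, times = NULL,
                                             minBins = 3L) {
  stopifnot(is(trace, "ComplexityTrace"))
  if (is(x, "DecodingResult")) {
    vals <- abs(x@corrT)
    times <- (seq_along(vals) - 1L) * x@dt
    step <- x@dt
  } else {
    vals <- as.numeric(x)
    if (is.null(times))
      stop("'times' is required when 'x' is a plain numeric series")
    if (length(times) != length(vals))
      stop("'times' must match the length of 'x'")
    step <- stats::median(diff(times))
  }
  tvals <- ifelse(trace@valid, trace@values, NA_real_)
  ttime <- (seq_along(tvals) - 1L) * trace@dt
  ## block-average the trace onto [t, t + step) for each reliability bin
  idx <- findInterval(ttime, c(times, times[length(times)] + step))
  ok <- idx >= 1L & idx <= length(times) &
    (ttime - times[pmax(idx, 1L)]) < step + 1e-12
  agg <- rep(NA_real_, length(times))
  if (any(ok)) {
    sums <- tapply(tvals[ok], idx[ok], function(v) mean(v, na.rm = TRUE))
    agg[as.integer(names(sums))] <- as.numeric(sums)
  }
  use <- is.finite(vals) & is.finite(agg)
  n <- sum(use)
  if (n < minBins)
    stop(sprintf("only %d overlapping valid bins (need >= %d)", n, minBins))
  if (sd(vals[use]) < 1e-14 || sd(agg[use]) < 1e-14)
    return(list(r = NA_real_, n = n))
  list(r = cor(vals[use], agg[use]), n = n)
}
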