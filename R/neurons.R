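#' @include AllClasses.R utils.R
NULL

#' Construct an encoder specification
#'
#' @param kind \code{"lnp"} or \code{"poisson"}.
#' @param baselineRate spontaneous rate (spikes/s).
#' @param gain evoked spikes/s per unit filter drive (LNP only).
#' @param bf best frequency (Hz).
#' @param bandwidth tuning SD in octaves.
#' @param latency response latency (s).
#' @param kernelWidth temporal integration SD (s).
#' @param jitter spike-time jitter SD (s).
#' @param refractory absolute refractory period (s).
#' @param seed integer seed.
#' @return an \linkS4class{EncoderSpec}.
#' @examples
#' spec <- encoderSpec(bf = 16000, gain = 80, seed = 3)
#' @export
encoderSpec <- function(kind = c("lnp", "poisson"), baselineRate = 2,
                        gain = 50, bf = 16000, bandwidth = 0.5,
                        latency = 0.015, kernelWidth = 0.005, jitter = 0,
                        refractory = 0.001, seed = 1L) {
  kind <- match.arg(kind)
  new("EncoderSpec", kind = kind, baselineRate = baselineRate, gain = gain,
      bf = bf, bandwidth = bandwidth, latency = latency,
      kernelWidth = kernelWidth, jitter = jitter, refractory = refractory,
      seed = as.integer(seed))
}

#' Simulate a homogeneous Poisson spike train
#'
#' The null model for calibrating the NCR significance threshold: spikes at
#' a constant rate, independent of the stimulus.
#'
#' @param rate firing rate (spikes/s), >= 0.
#' @param duration train duration (s).
#' @param seed integer seed.
#' @param unitId label.
#' @return a \linkS4class{SpikeTrain}.
#' @examples
#' tr <- simulatePoisson(20, 10, seed = 1)
#' length(spikeTimes(tr)) / duration(tr)
#' @export
simulatePoisson <- function(rate, duration, seed = 1L,
                            unitId = "poisson") {
  assertScalar(rate, "rate", nonneg = TRUE)
  assertScalar(duration, "duration", positive = TRUE)
  times <- withSeed(seed, {
    n <- rpois(1L, rate * duration)
    sort(runif(n, 0, duration))
  })
  new("SpikeTrain", times = times, duration = duration, unitId = unitId)
}

# instantaneous firing rate of an LNP encoder driven by a spectrogram,
# on the spectrogram time grid: baseline + gain * rectify(G (*) S)(t - latency)
# with G a separable Gaussian (unit-sum in each dimension).
lnpRate <- function(spec, stimulus) {
  ctr <- stimulus@axis@centers
  if (spec@bf < min(ctr) || spec@bf > max(ctr))
    stop(sprintf("encoder bf (%.0f Hz) lies outside the stimulus band (%.0f-%.0f Hz)",
                 spec@bf, min(ctr), max(ctr)))
  wf <- dnorm(log2(ctr), log2(spec@bf), spec@bandwidth)
  wf <- wf / sum(wf)
  drive <- as.numeric(wf %*% stimulus@energy)
  dt <- stimulus@dt
  ht <- max(1L, ceiling(4 * spec@kernelWidth / dt))
  wt <- dnorm(seq(-ht, ht) * dt, 0, max(spec@kernelWidth, dt / 10))
  wt <- wt / sum(wt)
  padded <- c(rep(0, ht), drive, rep(0, ht))
  sm <- stats::filter(padded, wt, method = "convolution", sides = 2)
  drive <- as.numeric(sm[(ht + 1L):(ht + length(drive))])
  lagBins <- round(spec@latency / dt)
  if (lagBins > 0)
    drive <- c(rep(0, lagBins), drive[seq_len(length(drive) - lagBins)])
  spec@baselineRate + spec@gain * pmax(drive, 0)
}

#' Simulate a linear-nonlinear-Poisson (LNP) unit
#'
#' A tuned model neuron with controllable ground truth, standing in for
#' recorded units: the stimulus is filtered by a separable Gaussian
#' spectrotemporal kernel (SD \code{bandwidth} octaves in log-frequency,
#' SD \code{kernelWidth} s in time, unit sum in each dimension), half-wave
#' rectified, delayed by \code{latency} and scaled by \code{gain} on top of
#' \code{baselineRate}. Spikes are drawn as an inhomogeneous Poisson process
#' (per-bin Bernoulli at a fine step with rate*dt kept well below 1), then
#' jittered by Gaussian noise and pruned to the absolute refractory period.
#'
#' @param spec an \linkS4class{EncoderSpec} with \code{kind = "lnp"}.
#' @param stimulus a \linkS4class{Spectrogram} whose band covers
#'   \code{spec@bf}.
#' @param simDt Bernoulli sampling step (s).
#' @return a \linkS4class{SpikeTrain}.
#' @examples
#' sw <- generateRDS(duration = 5, seed = 1)
#' sp <- renderSpectrogram(sw, dt = 0.005)
#' tr <- simulateLNP(encoderSpec(bf = 16000, gain = 80, seed = 2), sp)
#' @export
simulateLNP <- function(spec, stimulus, simDt = 5e-4) {
  stopifnot(is(spec, "EncoderSpec"), is(stimulus, "Spectrogram"))
  if (spec@kind != "lnp") stop("'spec' must have kind = 'lnp'")
  rate <- lnpRate(spec, stimulus)
  dur <- duration(stimulus)
  tGrid <- (seq_along(rate) - 0.5) * stimulus@dt
  nb <- floor(dur / simDt)
  tb <- (seq_len(nb) - 0.5) * simDt
  rb <- approx(tGrid, rate, xout = tb, rule = 2)$y
  p <- rb * simDt
  if (max(p) > 0.1)
    warning(sprintf("rate*dt reaches %.2f; Bernoulli sampling is a poor Poisson approximation above 0.1",
                    max(p)))
  times <- withSeed(spec@seed, {
    hit <- runif(nb) < p
    tt <- (which(hit) - 1L) * simDt + runif(sum(hit)) * simDt
    if (spec@jitter > 0) {
      tt <- tt + rnorm(length(tt), 0, spec@jitter)
      tt <- tt[tt >= 0 & tt <= dur]
    }
    sort(tt)
  })
  if (spec@refractory > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= spec@refractory) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  new("SpikeTrain", times = times, duration = dur,
      unitId = sprintf("lnp_bf%.0f_seed%d", spec@bf, spec@seed))
}

#' Merge spike trains into one multiunit train
#'
#' Emulates a multiunit gathering the activity of several single units
#' recorded at one site: the sorted union of all spike times.
#'
#' @param trains list of \linkS4class{SpikeTrain} with equal durations.
#' @param unitId label for the merged train.
#' @return a \linkS4class{SpikeTrain} whose spike count is the sum of the
#'   input counts.
#' @export
mergeUnits <- function(trains, unitId = "multiunit") {
  if (!length(trains) || !all(vapply(trains, is, TRUE, "SpikeTrain")))
    stop("'trains' must be a non-empty list of SpikeTrain objects")
  durs <- vapply(trains, duration, numeric(1))
  if (max(durs) - min(durs) > 1e-9)
    stop("all trains must share the same duration")
  new("SpikeTrain", times = sort(unlist(lapply(trains, spikeTimes))),
      duration = durs[1], unitId = unitId)
}

#' Mean evoked firing rate of a spike train
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @return spike count divided by duration (spikes/s).
#' @export
meanEvokedRate <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  length(train@times) / train@duration
}
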