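#' @include AllClasses.R utils.R
NULL

#' Construct a log-spaced frequency axis
#'
#' @param fmin,fmax band limits in Hz.
#' @param nChannels number of channels.
#' @return a \linkS4class{FrequencyAxis} with log2-uniform centers. The
#'   default reproduces the 45-channel, 2-90 kHz (5.5 octave) analysis axis.
#' @examples
#' ax <- logFrequencyAxis()
#' length(frequencyCenters(ax))
#' @export
logFrequencyAxis <- function(fmin = 2000, fmax = 90000, nChannels = 45L) {
  assertScalar(fmin, "fmin", positive = TRUE)
  assertScalar(fmax, "fmax", positive = TRUE)
  if (fmin >= fmax) stop("'fmin' must be smaller than 'fmax'")
  centers <- 2^seq(log2(fmin), log2(fmax), length.out = as.integer(nChannels))
  new("FrequencyAxis", centers = centers)
}

# octave spacing between adjacent channels
axisSpacing <- function(axis) {
  ctr <- axis@centers
  (log2(ctr[length(ctr)]) - log2(ctr[1])) / (length(ctr) - 1L)
}

# reflect values into [lo, hi]
reflectInto <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Generate a random double sweep (RDS) stimulus
#'
#' Two independent pure-tone voices whose log2-frequencies wander randomly
#' across a band, with all frequency-modulation power confined below a
#' cutoff. Each voice is a reflected integrated process: its FM velocity is
#' seeded Gaussian white noise low-pass filtered in the Fourier domain at
#' \code{speedCutoff} (zero-phase) and scaled to \code{rmsSpeed}; the
#' trajectory integrates this velocity from a seeded uniform starting
#' frequency and is reflected at the band edges. A reflected random walk
#' has a uniform stationary distribution, so the voices cover the whole
#' band evenly (as a band-covering sweep stimulus must), and because the
#' trajectory spectrum falls as 1/f^2 below the cutoff, the reflections
#' contribute negligible FM power above it.
#'
#' @param duration stimulus duration (s); the reference protocol is 300 s.
#' @param trajectoryDt trajectory sampling step (s).
#' @param fmin,fmax band limits (Hz), default 2-90 kHz.
#' @param speedCutoff FM low-pass cutoff (Hz), default 10 Hz.
#' @param seed integer seed; the same seed reproduces the pair bit for bit.
#' @param rmsSpeed RMS FM speed in octaves/s. The default (10 oct/s) makes
#'   a voice traverse the 5.5-octave band on a ~3 s timescale, matching the
#'   band-sweeping pace visible in published excerpts of this stimulus
#'   class.
#' @return a \linkS4class{SweepPair}.
#' @examples
#' sw <- generateRDS(duration = 10, seed = 1)
#' duration(sw)
#' @export
generateRDS <- function(duration = 300, trajectoryDt = 0.001, fmin = 2000,
                        fmax = 90000, speedCutoff = 10, seed = 1L,
                        rmsSpeed = 10) {
  assertScalar(duration, "duration", positive = TRUE)
  assertScalar(trajectoryDt, "trajectoryDt", positive = TRUE)
  assertScalar(speedCutoff, "speedCutoff", positive = TRUE)
  assertScalar(rmsSpeed, "rmsSpeed", positive = TRUE)
  if (fmin >= fmax) stop("'fmin' must be smaller than 'fmax'")
  n <- round(duration / trajectoryDt)
  if (n < 4L) stop("duration too short for the trajectory step")
  lo <- log2(fmin); hi <- log2(fmax)
  # per-sample frequency of FFT bin k (two-sided)
  fbin <- seq_len(n) - 1L
  fbin <- pmin(fbin, n - fbin) / (n * trajectoryDt)
  keep <- fbin <= speedCutoff
  mkVoice <- function() {
    v <- rnorm(n)
    V <- fft(v)
    V[!keep] <- 0+0i
    v <- Re(fft(V, inverse = TRUE)) / n
    m <- sd(v)
    if (m > 0) v <- v * (rmsSpeed / m)
    x <- runif(1, lo, hi) + cumsum(v) * trajectoryDt
    reflectInto(x, lo, hi)
  }
  log2f <- withSeed(seed, rbind(mkVoice(), mkVoice()))
  new("SweepPair", log2f = log2f, dt = trajectoryDt,
      bounds = c(fmin, fmax), speedCutoff = speedCutoff,
      seed = as.integer(seed))
}

#' Render a sweep pair as a spectrogram
#'
#' Each voice leaves a Gaussian ridge in log-frequency centered on its
#' instantaneous frequency, with unit peak energy. Coincident voices are
#' combined by maximum (default), so two voices at the same frequency do
#' not double the energy.
#'
#' With \code{equalize = TRUE} (the default) each channel row is divided
#' by its long-run mean energy, emulating the flat-spectrum speaker
#' calibration of the recording protocol this stimulus reproduces. Without
#' it, band-edge channels are systematically dimmer (ridge mass falls
#' outside the band) and the band occupancy of a finite realization is
#' never exactly flat; that static channel profile is inherited by any
#' average of stimulus segments and therefore correlates every
#' reconstruction -- including reconstructions from stimulus-independent
#' spike trains -- with the actual stimulus. Equalization removes this
#' shared static profile so that decoding scores reflect time-frequency
#' structure. The per-channel boost is capped at 20x to keep short
#' renderings (channels barely visited) finite.
#'
#' @param sweeps a \linkS4class{SweepPair}.
#' @param axis a \linkS4class{FrequencyAxis}.
#' @param dt spectrogram time step (s); must be an integer multiple of the
#'   trajectory step (trajectory samples are averaged within each column).
#' @param ridgeWidth SD of the ridge in octaves.
#' @param combine \code{"max"} (default) or \code{"sum"} for coincident
#'   voices.
#' @param equalize divide each channel row by its long-run mean energy.
#' @return a \linkS4class{Spectrogram}.
#' @examples
#' sw <- generateRDS(duration = 5, seed = 1)
#' sp <- renderSpectrogram(sw, dt = 0.005)
#' dim(energy(sp))
#' @export
renderSpectrogram <- function(sweeps, axis = logFrequencyAxis(), dt = 0.005,
                              ridgeWidth = 0.15, combine = c("max", "sum"),
                              equalize = TRUE) {
  stopifnot(is(sweeps, "SweepPair"))
  combine <- match.arg(combine)
  assertScalar(ridgeWidth, "ridgeWidth", positive = TRUE)
  ratio <- dt / sweeps@dt
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("'dt' must be a positive integer multiple of the trajectory step")
  ratio <- as.integer(round(ratio))
  n <- ncol(sweeps@log2f)
  nt <- n %/% ratio
  if (nt < 1L) stop("spectrogram would be empty at this dt")
  lctr <- log2(axis@centers)
  voiceCol <- function(v) {
    x <- sweeps@log2f[v, seq_len(nt * ratio)]
    colMeans(matrix(x, nrow = ratio))
  }
  ridge <- function(lv)
    exp(-(outer(lctr, lv, "-"))^2 / (2 * ridgeWidth^2))
  e1 <- ridge(voiceCol(1L))
  e2 <- ridge(voiceCol(2L))
  en <- if (combine == "max") pmax(e1, e2) else e1 + e2
  if (equalize) {
    rm <- rowMeans(en)
    en <- en / pmax(rm, 0.05 * mean(rm)) * mean(en)
  }
  new("Spectrogram", energy = en, dt = dt, axis = axis)
}

#' Generate a randomized pure-tone schedule
#'
#' Tones at the axis center frequencies, each presented \code{nReps} times
#' in seeded random order at a fixed presentation rate. The defaults
#' reproduce the receptive-field mapping protocol: 45 frequencies at
#' 4.15 Hz, eight repetitions each.
#'
#' @param axis a \linkS4class{FrequencyAxis}.
#' @param rate presentation rate (Hz).
#' @param nReps repetitions per frequency.
#' @param seed integer ordering seed.
#' @return a \linkS4class{ToneSchedule}.
#' @examples
#' sch <- generateToneSchedule(seed = 1)
#' nrow(sch@events)
#' @export
generateToneSchedule <- function(axis = logFrequencyAxis(), rate = 4.15,
                                 nReps = 8L, seed = 1L) {
  assertScalar(rate, "rate", positive = TRUE)
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("'nReps' must be >= 1")
  freqs <- rep(axis@centers, nReps)
  ord <- withSeed(seed, sample(length(freqs)))
  freqs <- freqs[ord]
  rep_idx <- stats::ave(seq_along(freqs), freqs, FUN = seq_along)
  events <- data.frame(onset_s = (seq_along(freqs) - 1L) / rate,
                       freq_hz = freqs, rep = as.integer(rep_idx))
  new("ToneSchedule", events = events, rate = rate,
      nFreqs = length(axis@centers), nReps = nReps, seed = as.integer(seed))
}

#' Render a tone schedule as a spectrogram
#'
#' Tones are rendered as rectangular-duration Gaussian ridges (no temporal
#' envelope modeling): each event deposits a unit-peak ridge at its
#' frequency for \code{toneDuration} seconds from its onset.
#'
#' @param schedule a \linkS4class{ToneSchedule}.
#' @param axis a \linkS4class{FrequencyAxis}.
#' @param dt time step (s).
#' @param toneDuration tone length (s), default 50 ms.
#' @param ridgeWidth ridge SD in octaves.
#' @return a \linkS4class{Spectrogram} spanning the schedule duration.
#' @export
renderToneSpectrogram <- function(schedule, axis = logFrequencyAxis(),
                                  dt = 0.001, toneDuration = 0.05,
                                  ridgeWidth = 0.15) {
  stopifnot(is(schedule, "ToneSchedule"))
  assertScalar(toneDuration, "toneDuration", positive = TRUE)
  nt <- ceiling(duration(schedule) / dt)
  lctr <- log2(axis@centers)
  en <- matrix(0, length(lctr), nt)
  lcols <- max(1L, round(toneDuration / dt))
  for (i in seq_len(nrow(schedule@events))) {
    c0 <- floor(schedule@events$onset_s[i] / dt) + 1L
    cols <- c0:min(c0 + lcols - 1L, nt)
    prof <- exp(-(lctr - log2(schedule@events$freq_hz[i]))^2 /
                  (2 * ridgeWidth^2))
    en[, cols] <- pmax(en[, cols], prof)
  }
  new("Spectrogram", energy = en, dt = dt, axis = axis)
}
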