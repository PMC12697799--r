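# shared small fixtures, built once per test run

# short RDS stimulus for decoder tests (20 s keeps every decode well under
# a second while leaving ~1991 candidate windows at the default stride)
fixtureStimulus <- local({
  cache <- NULL
  function(duration = 20, seed = 101L, dt = 0.005) {
    key <- paste(duration, seed, dt)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      sp <- renderSpectrogram(generateRDS(duration = duration, seed = seed),
                              dt = dt)
      attr(sp, "key") <- key
      cache <<- sp
    }
    cache
  }
})

fixtureParams <- function(k = 20L, ...) {
  ncrParams(k = k, keepPrediction = FALSE, ...)
}

# a spike train with given times (validity-checked)
mkTrain <- function(times, duration, id = "u") {
  new("SpikeTrain", times = times, duration = duration, unitId = id)
}

# the discretized Hann taper used by the temporal code, built directly
# from its closed form (independent oracle for distance values)
oracleHann <- function(ntaps = 19L) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(ntaps - 1L)) / (ntaps - 1L)))
  w / max(w)
}
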