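#' @include AllClasses.R
NULL

#' Read spike trains from a CSV or JSON table
#'
#' Expects one row per spike with columns \code{unit_id} and \code{time_s}
#' (CSV), or the equivalent named JSON arrays/records. Rows with negative
#' times raise an error naming the line; times unsorted within a unit are
#' sorted with a warning.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @param duration recording duration (s); inferred as the latest spike
#'   time (with a warning) when missing.
#' @return named list of \linkS4class{SpikeTrain}, one per unit.
#' @export
readSpikeTrains <- function(path, duration = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) {
    warning("empty spike table")
    return(list())
  }
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("spike table must have columns unit_id and time_s")
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad))
    stop(sprintf("negative or malformed time_s at line(s) %s",
                 paste(head(bad + 1L, 5L), collapse = ", ")))
  if (is.null(duration)) {
    duration <- max(df$time_s)
    warning(sprintf("duration inferred from the latest spike (%.3f s)",
                    duration))
  }
  out <- lapply(split(df$time_s, df$unit_id), function(tt) {
    if (is.unsorted(tt)) {
      warning("spike times were not sorted within a unit; sorting")
      tt <- sort(tt)
    }
    tt
  })
  mapply(function(tt, id) new("SpikeTrain", times = tt, duration = duration,
                              unitId = id),
         out, names(out), SIMPLIFY = FALSE)
}

#' Write spike trains to a CSV table
#'
#' @param trains list of \linkS4class{SpikeTrain}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSpikeTrains <- function(trains, path) {
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(u)
    if (length(u@times))
      data.frame(unit_id = u@unitId, time_s = u@times) else NULL))
  if (is.null(df)) df <- data.frame(unit_id = character(0),
                                    time_s = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a spectrogram as a named-array JSON container
#'
#' Fields: \code{energy} (channels x time), \code{dt}, and
#' \code{freq_centers_hz}.
#'
#' @param x a \linkS4class{Spectrogram}.
#' @param path \code{.json} path.
#' @return \code{writeSpectrogram}: the path, invisibly;
#'   \code{readSpectrogram}: a \linkS4class{Spectrogram}.
#' @export
writeSpectrogram <- function(x, path) {
  stopifnot(is(x, "Spectrogram"))
  jsonlite::write_json(list(energy = x@energy, dt = x@dt,
                            freq_centers_hz = x@axis@centers),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSpectrogram
#' @export
readSpectrogram <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new("Spectrogram", energy = as.matrix(obj$energy), dt = obj$dt,
      axis = new("FrequencyAxis", centers = as.numeric(obj$freq_centers_hz)))
}

#' Write / read a sweep pair as a named-array JSON container
#'
#' Fields: \code{log2f} (2 x n), \code{trajectory_dt}, \code{bounds},
#' \code{speed_cutoff}, \code{seed}.
#'
#' @param x a \linkS4class{SweepPair}.
#' @param path \code{.json} path.
#' @return \code{writeSweepPair}: the path, invisibly;
#'   \code{readSweepPair}: a \linkS4class{SweepPair}.
#' @export
writeSweepPair <- function(x, path) {
  stopifnot(is(x, "SweepPair"))
  jsonlite::write_json(list(log2f = x@log2f, trajectory_dt = x@dt,
                            bounds = x@bounds, speed_cutoff = x@speedCutoff,
                            seed = x@seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSweepPair
#' @export
readSweepPair <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new("SweepPair", log2f = as.matrix(obj$log2f), dt = obj$trajectory_dt,
      bounds = as.numeric(obj$bounds), speedCutoff = obj$speed_cutoff,
      seed = as.integer(obj$seed))
}

#' Write / read a tone schedule as CSV
#'
#' Columns \code{onset_s}, \code{freq_hz}, \code{rep}; the presentation
#' rate is recovered from the onset spacing on read.
#'
#' @param x a \linkS4class{ToneSchedule}.
#' @param path \code{.csv} path.
#' @return \code{writeToneSchedule}: the path, invisibly;
#'   \code{readToneSchedule}: a \linkS4class{ToneSchedule}.
#' @export
writeToneSchedule <- function(x, path) {
  stopifnot(is(x, "ToneSchedule"))
  write.csv(x@events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeToneSchedule
#' @export
readToneSchedule <- function(path) {
  ev <- read.csv(path)
  rate <- 1 / stats::median(diff(ev$onset_s))
  new("ToneSchedule", events = ev, rate = rate,
      nFreqs = length(unique(ev$freq_hz)), nReps = max(ev$rep),
      seed = NA_integer_)
}

#' Write / read a window set as a named-array JSON container
#'
#' Fields: \code{starts}, \code{vectors}, \code{counts}, \code{code_kind},
#' \code{length}, \code{stride}, \code{unit_ids}, \code{duration},
#' \code{bin_dt}; optional masks are stored as named boolean arrays
#' alongside under \code{masks}.
#'
#' @param x a \linkS4class{WindowSet}.
#' @param path \code{.json} path.
#' @param masks optional named list of \linkS4class{WindowMask} to store
#'   alongside.
#' @return \code{writeWindowSet}: the path, invisibly;
#'   \code{readWindowSet}: a list with \code{windows} (the
#'   \linkS4class{WindowSet}) and \code{masks}.
#' @export
writeWindowSet <- function(x, path, masks = list()) {
  stopifnot(is(x, "WindowSet"))
  obj <- list(starts = x@starts, vectors = x@vectors, counts = x@counts,
              code_kind = x@codeKind, length = x@length,
              stride = x@stride, unit_ids = x@unitIds,
              duration = x@duration, bin_dt = x@binDt,
              masks = lapply(masks, function(m) {
                stopifnot(is(m, "WindowMask"))
                list(kind = m@kind, flags = m@flags)
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeWindowSet
#' @export
readWindowSet <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ws <- new("WindowSet", starts = as.numeric(obj$starts),
            length = obj$length, stride = obj$stride,
            codeKind = obj$code_kind, vectors = as.matrix(obj$vectors),
            counts = matrix(as.integer(as.matrix(obj$counts)),
                            nrow = length(obj$starts)),
            unitIds = as.character(obj$unit_ids), duration = obj$duration,
            binDt = obj$bin_dt)
  masks <- lapply(obj$masks, function(m)
    new("WindowMask", kind = m$kind, flags = as.logical(m$flags),
        params = list()))
  list(windows = ws, masks = masks)
}

#' Read a run configuration from YAML
#'
#' Returns the configuration with defaults filled in; unknown fields raise
#' an error so typos do not silently fall back to defaults. See
#' [runDemo()] for the recognized fields.
#'
#' @param path YAML file path.
#' @return named list (a valid \code{config} for [runDemo()]).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- demoConfig()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  out <- utils::modifyList(defaults, cfg)
  out
}
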