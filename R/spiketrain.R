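#' Conditional intensity function from a rate map and behavior
#'
#' Evaluates the normalized spatial profile at the animal's (normalized)
#' position, sampled at `simulation_rate` by linear interpolation of the
#' behavior trace, and rescales so that the session-average rate equals
#' `mean_rate` exactly.
#'
#' @param map a [rate_map()].
#' @param trace a [behavior_trace()].
#' @param mean_rate target session-mean firing rate in Hz (defaults to
#'   the map's `mean_rate`).
#' @param simulation_rate spike-simulation sampling rate in Hz
#'   (default 1000).
#' @return Object of class `cif`: list with `rate` (Hz per sample),
#'   `simulation_rate`, `duration`.
#' @export
build_cif <- function(map, trace, mean_rate = map$mean_rate,
                      simulation_rate = 1000) {
  stopifnot_scalar(mean_rate, "mean_rate", 0.1, 30)
  dur <- session_duration(trace)
  nt <- floor(dur * simulation_rate)
  t_ms <- (seq_len(nt) - 0.5) / simulation_rate
  pos <- stats::approx(trace$timestamps, trace$position, xout = t_ms,
                       rule = 2)$y
  prof <- evaluate_ratemap(map, pos / trace$track_length)
  rate <- prof * (mean_rate / mean(prof))
  structure(list(rate = rate, simulation_rate = simulation_rate,
                 duration = dur), class = "cif")
}

#' Spike trains and frame-binned series
#'
#' `spike_train` holds sorted spike times in seconds; `frame_series`
#' holds one value per mock imaging frame (AP counts, dF/F, or transient
#' indicators) at a fixed frame rate.
#'
#' @param times spike times in seconds.
#' @param duration session duration in seconds.
#' @param simulation_rate simulation sampling rate in Hz.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, duration, simulation_rate = 1000) {
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) > 0 && (times[1] < 0 || times[length(times)] > duration)) {
    stop("spike times must lie within the session", call. = FALSE)
  }
  structure(list(times = as.numeric(times), duration = duration,
                 simulation_rate = simulation_rate), class = "spike_train")
}

#' @param values per-frame values.
#' @param frame_rate frame rate in Hz (default 30).
#' @param start_time time of the first frame's left edge, seconds.
#' @param kind `"counts"`, `"dff"`, or `"indicator"`.
#' @rdname spike_train
#' @export
frame_series <- function(values, frame_rate = 30, start_time = 0,
                         kind = c("counts", "dff", "indicator")) {
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 start_time = start_time, kind = match.arg(kind)),
            class = "frame_series")
}

#' Generate an inhomogeneous Poisson spike train from a CIF
#'
#' Draws per-bin counts `Poisson(rate * dt)` at the simulation rate and
#' places spikes at bin centers; several spikes per bin are permitted.
#'
#' @param cif a [build_cif()] result.
#' @param seed RNG seed.
#' @return A [spike_train()].
#' @export
generate_spikes <- function(cif, seed = NULL) {
  if (any(cif$rate < 0)) stop("CIF must be non-negative", call. = FALSE)
  sr <- cif$simulation_rate
  with_seed(seed, {
    counts <- stats::rpois(length(cif$rate), cif$rate / sr)
    idx <- which(counts > 0L)
    times <- rep((idx - 0.5) / sr, counts[idx])
    spike_train(times, cif$duration, sr)
  })
}

#' Bin spike times into mock imaging frames
#'
#' Frames are half-open intervals `[t, t + 1/frame_rate)` anchored at the
#' session start, so total spikes are conserved exactly.
#'
#' @param train a [spike_train()].
#' @param frame_rate imaging frame rate in Hz (default 30).
#' @return A [frame_series()] of integer counts, length
#'   `floor(duration * frame_rate)`.
#' @export
bin_to_frames <- function(train, frame_rate = 30) {
  stopifnot_scalar(frame_rate, "frame_rate", 1e-9, Inf)
  n_frames <- floor(train$duration * frame_rate)
  f <- floor(train$times * frame_rate) + 1L
  f <- f[f >= 1L & f <= n_frames]
  frame_series(tabulate(f, nbins = n_frames), frame_rate, 0, "counts")
}

#' Read or write spike-time lists (one time in seconds per line)
#'
#' This plain-text format is also the entry point for applying the
#' fluorescence-synthesis and estimation pipeline to real AP datasets.
#'
#' @param train a [spike_train()] (for writing).
#' @param path file path.
#' @param duration session duration in seconds (for reading).
#' @return `read_spike_times()` returns a [spike_train()].
#' @export
read_spike_times <- function(path, duration) {
  times <- scan(path, quiet = TRUE)
  spike_train(times, duration)
}

#' @rdname read_spike_times
#' @export
write_spike_times <- function(train, path) {
  writeLines(format(train$times, digits = 12, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}
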