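#' Linear-track behavior traces
#'
#' A `behavior_trace` holds uniformly sampled 1-D track position for a
#' head-fixed virtual linear-track session: the animal runs forward along
#' a 3-m track, is rewarded at the end, and after a short delay is
#' teleported back to the start of the track.
#'
#' @param position positions in meters, `0 <= position < track_length`.
#' @param sample_rate sampling rate in Hz.
#' @param track_length track length in meters (default 3).
#' @param lap_starts sample indices at which a new lap begins (the sample
#'   right after each teleport); index 1 is implicit and not stored.
#' @return Object of class `behavior_trace` with fields `timestamps`,
#'   `position`, `sample_rate`, `track_length`, `lap_starts`.
#' @export
behavior_trace <- function(position, sample_rate, track_length = 3,
                           lap_starts = integer(0)) {
  if (any(position < 0 | position >= track_length)) {
    stop("positions must satisfy 0 <= position < track_length", call. = FALSE)
  }
  if (any(diff(lap_starts) <= 0)) {
    stop("lap_starts must be strictly increasing", call. = FALSE)
  }
  n <- length(position)
  structure(
    list(timestamps = (seq_len(n) - 1) / sample_rate,
         position = as.numeric(position),
         sample_rate = sample_rate, track_length = track_length,
         lap_starts = as.integer(lap_starts)),
    class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace: %.1f min at %g Hz, %d laps, %g-m track>\n",
              length(x$position) / x$sample_rate / 60, x$sample_rate,
              length(x$lap_starts) + 1L, x$track_length))
  invisible(x)
}

session_duration <- function(trace) length(trace$position) / trace$sample_rate

#' Synthesize virtual linear-track behavior
#'
#' Generates forward-only running with Ornstein--Uhlenbeck speed
#' fluctuation around `mean_speed` (clipped at 0), Poisson-arriving
#' pauses with exponential durations, and an end-of-track reward stop
#' followed by teleportation to position 0 after `teleport_delay`
#' seconds.  Defaults mirror the treadmill statistics the simulations
#' emulate: a 3-m track, a 1.5-s teleport delay, ~22 cm/s running with
#' occasional pauses, giving ~19 cm/s overall track velocity and ~4
#' laps per minute.
#'
#' @param duration session duration in seconds.
#' @param mean_speed mean running speed in cm/s.
#' @param pause_rate Poisson rate of pause onsets per second of running.
#' @param pause_duration mean pause duration in seconds (exponential).
#' @param teleport_delay end-of-track stop before teleporting, seconds.
#' @param sample_rate behavior sampling rate in Hz.
#' @param track_length track length in meters.
#' @param speed_sd,speed_tau OU fluctuation SD (cm/s) and time constant (s).
#' @param seed RNG seed.
#' @return A [behavior_trace()].
#' @export
synth_behavior <- function(duration, mean_speed = 22, pause_rate = 1 / 30,
                           pause_duration = 2, teleport_delay = 1.5,
                           sample_rate = 50, track_length = 3,
                           speed_sd = 4, speed_tau = 2, seed = NULL) {
  stopifnot_scalar(duration, "duration", 1e-9, Inf)
  stopifnot_scalar(mean_speed, "mean_speed", 1e-9, Inf)
  n <- floor(duration * sample_rate)
  dt <- 1 / sample_rate
  hold_n <- as.integer(round(teleport_delay * sample_rate))
  with_seed(seed, {
    # OU speed fluctuation around mean_speed, clipped at 0 (cm/s),
    # generated for the whole session in one recursive filter pass
    ar <- 1 - dt / speed_tau
    innov <- speed_sd * sqrt(2 * dt / speed_tau) * stats::rnorm(n)
    v <- mean_speed + as.numeric(stats::filter(innov, ar, method = "recursive"))
    v <- pmax(v, 0)
    # Poisson-arriving pauses: speed forced to 0 for the pause duration
    onsets <- which(stats::runif(n) < pause_rate * dt)
    if (length(onsets) > 0) {
      durs <- pmax(1L, as.integer(round(
        stats::rexp(length(onsets), 1 / pause_duration) * sample_rate)))
      for (k in seq_along(onsets)) {
        v[onsets[k]:min(n, onsets[k] + durs[k] - 1L)] <- 0
      }
    }
    steps <- v / 100 * dt                     # meters per sample
    pos <- numeric(n)
    lap_starts <- integer(0)
    i <- 1L                                   # write pointer (time samples)
    src <- 1L                                 # read pointer into the speed draw
    top <- track_length * (1 - 1e-12)
    while (i <= n) {
      avail <- n - i + 1L
      cs <- cumsum(steps[src:(src + avail - 1L)])
      j <- match(TRUE, cs >= track_length)
      if (is.na(j)) {                         # session ends mid-lap
        pos[i:n] <- pmin(cs, top)
        break
      }
      pos[i:(i + j - 1L)] <- pmin(cs[seq_len(j)], top)
      i <- i + j
      src <- src + j
      if (i <= n) {                           # reward stop, then teleport to 0
        h <- min(hold_n, n - i + 1L)
        if (h > 0L) {
          pos[i:(i + h - 1L)] <- top
          i <- i + h
        }
        if (i <= n) lap_starts <- c(lap_starts, i)
      }
    }
    behavior_trace(pos, sample_rate, track_length, lap_starts)
  })
}

#' Concatenate behavior traces and truncate to a target duration
#'
#' Timestamps are re-based to a single session clock; per-sample
#' positions are preserved across joins (no interpolation), and
#' `lap_starts` are merged and re-indexed.  A join is also marked as a
#' lap start, since position jumps discontinuously there.
#'
#' @param traces list of [behavior_trace()]s sharing `sample_rate` and
#'   `track_length`.
#' @param target_duration desired total duration in seconds.
#' @return A [behavior_trace()] of `floor(target_duration * sample_rate)`
#'   samples.
#' @export
assemble_session <- function(traces, target_duration) {
  if (length(traces) == 0L) stop("empty trace list", call. = FALSE)
  sr <- traces[[1]]$sample_rate
  tl <- traces[[1]]$track_length
  for (tr in traces) {
    if (tr$sample_rate != sr || tr$track_length != tl) {
      stop("all traces must share sample_rate and track_length", call. = FALSE)
    }
  }
  pos <- unlist(lapply(traces, `[[`, "position"), use.names = FALSE)
  offs <- cumsum(c(0L, vapply(traces, function(t) length(t$position), 1L)))
  laps <- unlist(lapply(seq_along(traces), function(i) {
    ls <- traces[[i]]$lap_starts + offs[i]
    if (i > 1L) ls <- c(offs[i] + 1L, ls)   # join counts as a lap boundary
    ls
  }), use.names = FALSE)
  n <- floor(target_duration * sr)
  if (n > length(pos)) {
    stop("traces are shorter than the target duration", call. = FALSE)
  }
  laps <- sort(unique(laps[laps <= n]))
  behavior_trace(pos[seq_len(n)], sr, tl, laps)
}

#' Instantaneous track speed (cm/s)
#'
#' Centered finite difference of position, with samples adjacent to
#' teleport discontinuities masked to `NA` so that lap boundaries never
#' produce spurious +/- 3 m/sample speeds.
#'
#' @param trace a [behavior_trace()].
#' @return Numeric vector of speeds in cm/s (`NA` at teleports and ends).
#' @export
track_speed <- function(trace) {
  p <- trace$position
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 3L) {
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / 2 * trace$sample_rate * 100
  }
  # mask the samples whose centered difference straddles a teleport
  for (ls in trace$lap_starts) {
    idx <- (ls - 1L):ls
    idx <- idx[idx >= 1L & idx <= n]
    v[idx] <- NA_real_
  }
  v
}

#' Running-period mask
#'
#' Marks samples inside maximal contiguous epochs where the instantaneous
#' speed exceeds `speed_threshold` and the epoch covers at least
#' `min_run` cm of net forward distance.
#'
#' @param trace a [behavior_trace()].
#' @param speed_threshold speed threshold in cm/s (default 4).
#' @param min_run minimum continuous run distance in cm (default 40).
#' @return Logical vector, one element per behavior sample.
#' @export
run_mask <- function(trace, speed_threshold = 4, min_run = 40) {
  stopifnot_scalar(speed_threshold, "speed_threshold", 1e-12, Inf)
  stopifnot_scalar(min_run, "min_run", 1e-12, Inf)
  v <- track_speed(trace)
  fast <- !is.na(v) & v > speed_threshold
  mask <- logical(length(fast))
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    net <- (trace$position[ends[k]] - trace$position[starts[k]]) * 100
    if (net >= min_run) mask[starts[k]:ends[k]] <- TRUE
  }
  mask
}

#' Session-level inclusion criterion
#'
#' A session qualifies when it lasts between 5 and 30 minutes and
#' contains at least `min_laps` laps that each include a continuous
#' >= `min_run` cm run at speeds above `speed_threshold`.
#'
#' @param trace a [behavior_trace()].
#' @param speed_threshold qualifying speed in cm/s (default 7).
#' @param min_run qualifying run length in cm (default 40).
#' @param min_laps minimum number of qualifying laps (default 20).
#' @param duration_range allowed session duration, minutes.
#' @return `TRUE` or `FALSE`.
#' @export
session_inclusion <- function(trace, speed_threshold = 7, min_run = 40,
                              min_laps = 20, duration_range = c(5, 30)) {
  dur_min <- session_duration(trace) / 60
  if (dur_min < duration_range[1] || dur_min > duration_range[2]) return(FALSE)
  mask <- run_mask(trace, speed_threshold, min_run)
  bounds <- c(1L, trace$lap_starts, length(trace$position) + 1L)
  good <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    if (any(mask[bounds[k]:(bounds[k + 1L] - 1L)])) good <- good + 1L
  }
  good >= min_laps
}

#' Read or write behavior traces as two-column delimited text
#'
#' Files hold `time_s` and `position_m` columns; on read, positions are
#' resampled to `sample_rate` by linear interpolation.
#'
#' @param trace a [behavior_trace()] (for writing).
#' @param path file path.
#' @param sample_rate target sampling rate in Hz (for reading).
#' @param track_length track length in meters (for reading).
#' @return `read_behavior()` returns a [behavior_trace()];
#'   `write_behavior()` returns `path` invisibly.
#' @export
read_behavior <- function(path, sample_rate = 50, track_length = 3) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  t_out <- seq(0, max(df[[1]]), by = 1 / sample_rate)
  p <- stats::approx(df[[1]], df[[2]], xout = t_out, rule = 2)$y
  p <- pmin(pmax(p, 0), track_length * (1 - 1e-12))
  # recover teleports as large backward jumps
  laps <- which(diff(p) < -track_length / 2) + 1L
  behavior_trace(p, sample_rate, track_length, laps)
}

#' @rdname read_behavior
#' @export
write_behavior <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = trace$timestamps, position_m = trace$position),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
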