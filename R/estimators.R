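#' Binned occupancy and activity maps
#'
#' Bins the track into `n_bins` equal-width spatial bins (default 60,
#' i.e. 5-cm bins on a 3-m track) and computes, over run-masked frames,
#' the occupancy distribution \eqn{p_X(x_i)} and the per-bin mean
#' activity: the firing rate \eqn{\lambda_i} in Hz for AP-count series
#' (counts times the frame rate) or the mean \eqn{f_i} in dF/F for
#' fluorescence series.  Unoccupied bins are flagged and excluded from
#' all sums; occupancy is normalized over occupied bins.
#'
#' @param activity a [frame_series()] of counts or dF/F, temporally
#'   aligned with `trace`.
#' @param trace the session's [behavior_trace()].
#' @param mask optional logical run mask at the behavior sampling rate
#'   (see [run_mask()]); `NULL` uses all frames.
#' @param n_bins number of spatial bins (>= 2; default 60).
#' @return Object of class `spatial_maps`: `occupancy`, `activity`,
#'   `occupied`, `overall_mean`, `n_bins`, `source_units`, `frame_rate`.
#' @export
spatial_maps <- function(activity, trace, mask = NULL, n_bins = 60) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  n_frames <- length(activity$values)
  centers <- activity$start_time + (seq_len(n_frames) - 0.5) / activity$frame_rate
  pos <- stats::approx(trace$timestamps, trace$position, xout = centers,
                       rule = 2)$y
  keep <- rep(TRUE, n_frames)
  if (!is.null(mask)) {
    midx <- pmin(pmax(round(centers * trace$sample_rate + 0.5), 1L),
                 length(mask))
    keep <- mask[midx]
  }
  if (sum(keep) == 0L) stop("degenerate session: no masked frames", call. = FALSE)
  bin <- pmin(pmax(floor(pos / trace$track_length * n_bins) + 1L, 1L), n_bins)
  vals <- activity$values
  if (activity$kind == "counts") vals <- vals * activity$frame_rate  # -> Hz
  counts <- tabulate(bin[keep], nbins = n_bins)
  sums <- dense_group_sums(vals[keep], bin[keep], n_bins)
  occupied <- counts > 0L
  act <- numeric(n_bins)
  act[occupied] <- sums / counts[occupied]
  if (sum(occupied) < 2L) {
    stop("degenerate session: fewer than 2 occupied bins", call. = FALSE)
  }
  occ <- counts / sum(counts)
  structure(list(n_bins = n_bins, occupancy = occ, activity = act,
                 occupied = occupied,
                 overall_mean = sum(occ * act),
                 source_units = if (activity$kind == "counts") "hz" else "dff",
                 frame_rate = activity$frame_rate),
            class = "spatial_maps")
}

# rowsum() drops absent groups; rebuild a dense per-bin sum vector.
dense_group_sums <- function(x, group, n_bins) {
  out <- numeric(n_bins)
  s <- base::rowsum(x, group, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Construct spatial maps directly from per-bin values
#'
#' Convenience constructor for toy inputs and tests: supply the
#' occupancy and activity vectors yourself.
#'
#' @param occupancy per-bin occupancy probabilities (normalized
#'   internally over occupied bins).
#' @param activity per-bin mean activity (Hz or dF/F).
#' @param source_units `"hz"`, `"dff"`, or `"arbitrary"`.
#' @param frame_rate frame rate used for per-sample conversions.
#' @return A `spatial_maps` object.
#' @export
manual_maps <- function(occupancy, activity,
                        source_units = c("hz", "dff", "arbitrary"),
                        frame_rate = 30) {
  source_units <- match.arg(source_units)
  occ <- occupancy / sum(occupancy)
  structure(list(n_bins = length(occ), occupancy = occ,
                 activity = as.numeric(activity),
                 occupied = occ > 0,
                 overall_mean = sum(occ * activity),
                 source_units = source_units, frame_rate = frame_rate),
            class = "spatial_maps")
}

#' Rate-map information estimators (Skaggs-style), bits per second
#'
#' Evaluates \eqn{\hat I_s = \sum_i \lambda_i p_X(x_i) \log_2
#' (\lambda_i/\bar\lambda)} over occupied bins, where
#' \eqn{\bar\lambda = \sum_i p_X(x_i)\lambda_i}.  Bins with zero
#' activity contribute 0 (the \eqn{x \log x \to 0} limit).  For
#' fluorescence maps the same sum is computed with \eqn{f_i} and
#' \eqn{\bar f}; its nominal units are then a dF/F-scaled bit rate
#' rather than true bits/s.  Bin means that come out negative (possible
#' for noisy dF/F) are floored to 0 before the sum and the overall mean
#' is recomputed accordingly.
#'
#' @param maps a [spatial_maps()].
#' @return Object of class `mi_estimate`: list with `value`, `units`,
#'   `method`.
#' @export
smgm_bits_per_second <- function(maps) {
  p <- maps$occupancy[maps$occupied]
  p <- p / sum(p)
  act <- pmax(maps$activity[maps$occupied], 0)
  m <- sum(p * act)
  if (m <= 0) stop("overall mean activity must be positive", call. = FALSE)
  nz <- act > 0
  value <- sum(act[nz] * p[nz] * log2(act[nz] / m))
  mi_estimate(max(value, 0),
              units = if (maps$source_units == "hz") "bits_per_sec"
                      else "dff_bits_scaled",
              method = "smgm_sec")
}

#' Rate-map information per event (bits/AP)
#'
#' The bits-per-second sum normalized by the overall mean:
#' \eqn{\hat I_{AP} = \hat I_s / \bar\lambda}.  For fluorescence maps
#' the activity scale cancels, so the result is in bits/AP for both
#' sources and is invariant to multiplying the activity map by any
#' positive constant.
#'
#' @inheritParams smgm_bits_per_second
#' @return An `mi_estimate` in `bits_per_ap`.
#' @export
smgm_bits_per_ap <- function(maps) {
  p <- maps$occupancy[maps$occupied]
  p <- p / sum(p)
  act <- pmax(maps$activity[maps$occupied], 0)
  m <- sum(p * act)
  if (m <= 0) stop("overall mean activity must be positive", call. = FALSE)
  s <- smgm_bits_per_second(maps)
  mi_estimate(s$value / m, units = "bits_per_ap", method = "smgm_ap")
}

mi_estimate <- function(value, units, method) {
  structure(list(value = value, units = units, method = method),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate [%s]: %.5g %s>\n", x$method, x$value, x$units))
  invisible(x)
}

# Plug-in MI (bits per sample) of a joint count table.
plugin_mi <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  ex <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ex[nz]))
}

#' Binned (plug-in) mutual information estimator
#'
#' Discretizes the activity trace into `activity_bins` bins -- either
#' equal-width over the activity range (`"uniform"`) or equal-count
#' quantile bins (`"occupancy"`, right-closed edges with ties assigned
#' to the lower bin) -- forms the joint histogram against the spatial
#' bins, computes the plug-in MI in bits per sample, and scales by the
#' frame rate to report bits per second.  A constant activity trace has
#' MI 0 by definition.
#'
#' @param activity numeric per-frame activity values (or a
#'   [frame_series()]).
#' @param position_bins integer per-frame spatial bin indices.
#' @param activity_bins number of activity bins (default 10).
#' @param scheme `"uniform"` or `"occupancy"`.
#' @param frame_rate frames per second used for the bits/s conversion.
#' @return An `mi_estimate` (value in bits/s; `value / frame_rate` is
#'   bits per sample).
#' @export
binned_mi <- function(activity, position_bins, activity_bins = 10,
                      scheme = c("uniform", "occupancy"), frame_rate = 30) {
  scheme <- match.arg(scheme)
  if (activity_bins < 2) stop("activity_bins must be >= 2", call. = FALSE)
  x <- if (inherits(activity, "frame_series")) activity$values else activity
  if (diff(range(x)) == 0) {
    return(mi_estimate(0, "bits_per_sec",
                       paste0("binned_", scheme)))
  }
  if (scheme == "uniform") {
    breaks <- seq(min(x), max(x), length.out = activity_bins + 1L)
  } else {
    breaks <- stats::quantile(x, probs = seq(0, 1, length.out =
                                               activity_bins + 1L),
                              names = FALSE, type = 7)
    breaks <- unique(breaks)
  }
  ab <- .bincode(x, breaks, right = TRUE, include.lowest = TRUE)
  tab <- table(factor(position_bins), factor(ab))
  mi_estimate(plugin_mi(unclass(tab)) * frame_rate, "bits_per_sec",
              paste0("binned_", scheme))
}

#' KSG k-nearest-neighbor mutual information estimator (algorithm 2)
#'
#' Estimates MI between two continuous variables from k-nearest-neighbor
#' statistics under the max norm: for each point the per-coordinate
#' projected distances of its k-th neighborhood define marginal search
#' radii, marginal neighbor counts \eqn{n_x, n_y} are taken with
#' boundary points included, and
#' \deqn{\hat I = \psi(k) - 1/k - \langle \psi(n_x) + \psi(n_y)\rangle
#'   + \psi(N)} (converted to bits).  Duplicate-heavy input is broken by
#' a seeded uniform jitter of 1e-10 of the data range.
#'
#' @param activity,position numeric vectors of equal length.
#' @param k neighbor order (default 5).
#' @param frame_rate frames per second for the bits/s conversion.
#' @param jitter add tie-breaking jitter (default `TRUE`).
#' @param seed RNG seed for the jitter.
#' @return An `mi_estimate` (value in bits/s; `value / frame_rate` is
#'   bits per sample).
#' @export
ksg_mi <- function(activity, position, k = 5, frame_rate = 30,
                   jitter = TRUE, seed = NULL) {
  x <- if (inherits(activity, "frame_series")) activity$values else activity
  y <- as.numeric(position)
  n <- length(x)
  if (k < 1 || n < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  if (jitter) {
    eps_x <- 1e-10 * max(diff(range(x)), 1)
    eps_y <- 1e-10 * max(diff(range(y)), 1)
    jit <- with_seed(seed, stats::runif(2 * n, -1, 1))
    x <- x + eps_x * jit[seq_len(n)]
    y <- y + eps_y * jit[n + seq_len(n)]
  } else if (anyDuplicated(x) || anyDuplicated(y)) {
    warning("duplicate values without jitter can bias the KSG estimate")
  }
  nx <- ny <- integer(n)
  for (i in seq_len(n)) {
    dx <- abs(x - x[i]); dy <- abs(y - y[i])
    dj <- pmax(dx, dy); dj[i] <- Inf
    kth <- sort.int(dj, partial = k)[k]
    nb <- which(dj <= kth)
    if (length(nb) > k) nb <- nb[order(dj[nb])][seq_len(k)]
    ex <- max(dx[nb]); ey <- max(dy[nb])
    nx[i] <- sum(dx <= ex) - 1L
    ny[i] <- sum(dy <= ey) - 1L
  }
  val_bits <- (digamma(k) - 1 / k - mean(digamma(nx) + digamma(ny)) +
                 digamma(n)) / log(2)
  mi_estimate(val_bits * frame_rate, "bits_per_sec", "ksg")
}

#' Closed-form approximations for fluorescence information
#'
#' For a Gaussian firing field traversed at constant normalized speed
#' `v`, with a single-exponential kernel of time constant `tau` and
#' amplitude scale `A`, the measured fluorescence information can be
#' approximated in closed form.  Per second:
#' \deqn{I_s^F \approx -A v \tau \bar\lambda \,\log\!\big(4^{-I_s /
#'   \bar\lambda} + 2\pi e v^2 \tau^2\big) / \log 4,}
#' and per AP:
#' \deqn{I_{AP}^F \approx -\log\!\big(4^{-I_{AP}} + 2 e \pi v^2
#'   \tau^2\big) / \log 4.}
#' At `tau = 0` the per-AP form returns the true information exactly and
#' the per-second form vanishes through its prefactor.
#'
#' @param i_true ground-truth information (bits/s for
#'   `analytic_bits_per_second()`, bits/AP for `analytic_bits_per_ap()`).
#' @param mean_rate mean firing rate in Hz (per-second form only).
#' @param v normalized running speed (track lengths per second).
#' @param tau kernel time constant, seconds.
#' @param A kernel amplitude scale (per-second form only).
#' @return An `mi_estimate`.
#' @export
analytic_bits_per_second <- function(i_true, mean_rate, v, tau, A = 1) {
  stopifnot_scalar(tau, "tau", 0, Inf)
  stopifnot_scalar(v, "v", 1e-12, Inf)
  val <- -A * v * tau * mean_rate *
    log(4^(-i_true / mean_rate) + 2 * pi * exp(1) * v^2 * tau^2) / log(4)
  mi_estimate(val, "dff_bits_scaled", "analytic_sec")
}

#' @rdname analytic_bits_per_second
#' @export
analytic_bits_per_ap <- function(i_true, v, tau) {
  stopifnot_scalar(tau, "tau", 0, Inf)
  stopifnot_scalar(v, "v", 1e-12, Inf)
  val <- -log(4^(-i_true) + 2 * exp(1) * pi * v^2 * tau^2) / log(4)
  mi_estimate(val, "bits_per_ap", "analytic_ap")
}

#' Per-frame spatial bin indices for a session
#'
#' @param trace a [behavior_trace()].
#' @param n_frames number of frames.
#' @param frame_rate frame rate in Hz.
#' @param n_bins number of spatial bins.
#' @return Integer vector of bin indices at frame centers.
#' @export
frame_position_bins <- function(trace, n_frames, frame_rate = 30,
                                n_bins = 60) {
  centers <- (seq_len(n_frames) - 0.5) / frame_rate
  pos <- stats::approx(trace$timestamps, trace$position, xout = centers,
                       rule = 2)$y
  pmin(pmax(floor(pos / trace$track_length * n_bins) + 1L, 1L), n_bins)
}
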