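#' Significant-transient detection in dF/F traces
#'
#' Candidate events are contiguous excursions beyond +/- 2 sigma of the
#' noise.  Events are classified by peak amplitude (0.5-sigma steps from
#' 2 sigma) and duration (frames), and a positive class is accepted when
#' the ratio of negative-going to positive-going events at or above that
#' amplitude and duration falls below `target_fpr` -- negative
#' excursions cannot be real transients, so they estimate the false
#' positive rate of each class.  The returned mask marks frames inside
#' accepted positive events.
#'
#' @param trace a [frame_series()] of dF/F.
#' @param noise_sd_estimate noise SD in dF/F; estimated robustly from
#'   the trace (median absolute deviation) when `NULL`.
#' @param target_fpr acceptable false-positive rate (default 1e-4).
#' @return Object of class `transient_mask`: logical `mask` per frame,
#'   the accepted `threshold_table`, `target_fpr`, `noise_sd`.
#' @export
detect_transients <- function(trace, noise_sd_estimate = NULL,
                              target_fpr = 1e-4) {
  x <- trace$values
  sigma <- noise_sd_estimate %||% stats::mad(x)
  if (sigma <= 0 || all(x == 0)) {
    return(structure(list(mask = logical(length(x)),
                          threshold_table = NULL,
                          target_fpr = target_fpr, noise_sd = sigma),
                     class = "transient_mask"))
  }
  events <- function(sign_flip) {
    z <- sign_flip * x / sigma
    above <- z > 2
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               amp = vapply(keep, function(k)
                 max(z[starts[k]:ends[k]]), 1.0),
               dur = r$lengths[keep])
  }
  pos <- events(1)
  neg <- events(-1)
  if (nrow(pos) == 0L) {
    return(structure(list(mask = logical(length(x)),
                          threshold_table = NULL,
                          target_fpr = target_fpr, noise_sd = sigma),
                     class = "transient_mask"))
  }
  if (nrow(neg) < 10L) {
    # too few negative excursions to estimate class-wise false-positive
    # rates; fall back to a Gaussian-null analytic amplitude threshold
    warning("too few negative-going events; using Gaussian-null thresholds")
    thr <- stats::qnorm(1 - target_fpr)
    mask <- logical(length(x))
    keep <- pos$amp >= thr & pos$dur >= 2L
    for (e in which(keep)) mask[pos$start[e]:pos$end[e]] <- TRUE
    return(structure(list(mask = mask, threshold_table = NULL,
                          target_fpr = target_fpr, noise_sd = sigma,
                          events = pos[keep, , drop = FALSE]),
                     class = "transient_mask"))
  }
  # cumulative class counts: events with amplitude >= a AND duration >= d
  amp_grid <- seq(2, max(pos$amp, 2) + 0.5, by = 0.5)
  dur_grid <- sort(unique(pos$dur))
  accept <- matrix(FALSE, length(amp_grid), length(dur_grid))
  for (ai in seq_along(amp_grid)) {
    for (di in seq_along(dur_grid)) {
      np <- sum(pos$amp >= amp_grid[ai] & pos$dur >= dur_grid[di])
      nn <- sum(neg$amp >= amp_grid[ai] & neg$dur >= dur_grid[di])
      accept[ai, di] <- np > 0L && (nn / np) < target_fpr
    }
  }
  mask <- logical(length(x))
  acc_rows <- integer(0)
  for (e in seq_len(nrow(pos))) {
    ai <- findInterval(pos$amp[e], amp_grid)
    di <- findInterval(pos$dur[e], dur_grid)
    if (ai >= 1L && di >= 1L && accept[ai, di]) {
      mask[pos$start[e]:pos$end[e]] <- TRUE
      acc_rows <- c(acc_rows, e)
    }
  }
  tt <- expand.grid(amp = amp_grid, dur = dur_grid)
  tt$accepted <- as.vector(accept)
  structure(list(mask = mask, threshold_table = tt,
                 target_fpr = target_fpr, noise_sd = sigma,
                 events = pos[acc_rows, , drop = FALSE]),
            class = "transient_mask")
}

# Contiguous TRUE runs of a logical vector as (start, end) rows.
mask_events <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep], dur = r$lengths[keep])
}

#' Bootstrap place-field identification
#'
#' Builds the 60-bin spatial fluorescence map from the transient-masked
#' trace (3-bin boxcar smoothed), then builds `n_boot` surrogate maps by
#' shuffling transient events in order and re-placing them at random
#' positions within the run-period frames (event count and durations
#' preserved).  Candidate fields are contiguous bins where the original
#' map exceeds the per-bin 99th percentile of the surrogates; fields
#' between `width_range[1]` and `width_range[2]` cm wide are retained.
#' A neuron with at least one retained field is a place cell.
#'
#' @param dff a [frame_series()] of dF/F.
#' @param trace the session's [behavior_trace()].
#' @param transients a [detect_transients()] result (computed when
#'   `NULL`).
#' @param mask run-period mask at the behavior rate (computed when
#'   `NULL`).
#' @param n_bins spatial bins (default 60, 5-cm bins).
#' @param n_boot surrogate maps (default 1000).
#' @param width_range retained field width range in cm.
#' @param seed RNG seed for the shuffles.
#' @return List of class `place_fields`: `fields` (data frame with
#'   `start_bin`, `end_bin`, `width_cm`), `is_place_cell`, `map`,
#'   `threshold`.
#' @export
find_place_fields <- function(dff, trace, transients = NULL, mask = NULL,
                              n_bins = 60, n_boot = 1000,
                              width_range = c(20, 120), seed = NULL) {
  if (is.null(mask)) mask <- run_mask(trace)
  if (is.null(transients)) transients <- detect_transients(dff)
  n_frames <- length(dff$values)
  fr <- dff$frame_rate
  centers <- (seq_len(n_frames) - 0.5) / fr
  midx <- pmin(pmax(round(centers * trace$sample_rate + 0.5), 1L),
               length(mask))
  frame_run <- mask[midx]
  pbins <- frame_position_bins(trace, n_frames, fr, n_bins)
  run_frames <- which(frame_run)
  if (length(run_frames) < 2L) stop("no run-period frames", call. = FALSE)
  sig <- transients$mask & frame_run
  ev <- mask_events(sig)
  if (nrow(ev) == 0L) {
    return(structure(list(fields = data.frame(start_bin = integer(0),
                                              end_bin = integer(0),
                                              width_cm = numeric(0)),
                          is_place_cell = FALSE, map = rep(0, n_bins),
                          threshold = rep(NA_real_, n_bins)),
                     class = "place_fields"))
  }
  boxcar <- function(v) {
    out <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    out[1] <- mean(v[1:2]); out[length(v)] <- mean(v[(length(v) - 1):length(v)])
    as.numeric(out)
  }
  occ_all <- tabulate(pbins[run_frames], n_bins)
  field_map <- function(sig_frames) {
    hits <- tabulate(pbins[sig_frames], n_bins)
    boxcar(ifelse(occ_all > 0, hits / pmax(occ_all, 1), 0))
  }
  orig <- field_map(which(sig))
  bin_cm <- trace$track_length * 100 / n_bins
  surr <- with_seed(seed, {
    nrun <- length(run_frames)
    vapply(seq_len(n_boot), function(b) {
      ord <- sample.int(nrow(ev))       # shuffle event order
      frames <- integer(0)
      for (e in ord) {
        d <- ev$dur[e]
        at <- sample.int(max(nrun - d, 1L), 1L)  # random interval in run time
        frames <- c(frames, run_frames[at:min(at + d - 1L, nrun)])
      }
      field_map(unique(frames))
    }, numeric(n_bins))
  })
  thr <- apply(surr, 1, stats::quantile, probs = 0.99, names = FALSE)
  above <- orig > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  fields <- data.frame(start_bin = starts[keep], end_bin = ends[keep],
                       width_cm = r$lengths[keep] * bin_cm)
  fields <- fields[fields$width_cm >= width_range[1] &
                     fields$width_cm <= width_range[2], , drop = FALSE]
  structure(list(fields = fields, is_place_cell = nrow(fields) > 0L,
                 map = orig, threshold = thr),
            class = "place_fields")
}

#' Bayesian position decoding from significant-frame populations
#'
#' Each neuron contributes its significant-transient indicator series.
#' Rate maps \eqn{f_{i,j}} (significant frames per second of occupancy
#' in spatial bin i, neuron j) are estimated on the training portion of
#' the session; on each test window of `window` seconds the posterior
#' over position bins is
#' \deqn{p(x_i \mid n) \propto p_X(x_i)\Big(\prod_j f_{i,j}^{n_j}\Big)
#'   e^{-\Delta t \sum_j f_{i,j}},}
#' accumulated in the log domain, with \eqn{n_j} the number of
#' significant frames of neuron j in the window.  The decoded bin is the
#' posterior argmax; windows with no likelihood mass anywhere fall back
#' to the occupancy-prior argmax and are flagged.
#'
#' @param population list of per-neuron significant-frame masks (logical
#'   vectors or [detect_transients()] results), all at `frame_rate`.
#' @param trace the session's [behavior_trace()].
#' @param window decoding window in seconds (default 0.1).
#' @param train_fraction leading fraction of the session used to fit the
#'   maps (default 0.8; test is the rest).
#' @param n_bins spatial bins (default 60).
#' @param frame_rate frame rate of the masks, Hz.
#' @param rate_floor small floor (Hz) added to the per-neuron maps so
#'   log-likelihoods stay finite.
#' @return Object of class `decode_result`: data frame `windows`
#'   (`decoded_bin`, `truth_bin`, `abs_error_pct`, `flagged`), plus
#'   `median_abs_error_pct`, `window`, `train_fraction`.
#' @export
bayes_decode <- function(population, trace, window = 0.1,
                         train_fraction = 0.8, n_bins = 60,
                         frame_rate = 30, rate_floor = 1e-3) {
  if (length(population) < 1L) stop("need at least one neuron", call. = FALSE)
  masks <- lapply(population, function(p) {
    if (inherits(p, "transient_mask")) p$mask
    else if (inherits(p, "frame_series")) p$values > 0
    else as.logical(p)
  })
  n_frames <- min(vapply(masks, length, 1L))
  pbins <- frame_position_bins(trace, n_frames, frame_rate, n_bins)
  split_at <- floor(train_fraction * n_frames)
  train <- seq_len(split_at)
  test <- (split_at + 1L):n_frames
  occ_counts <- tabulate(pbins[train], n_bins)
  prior <- occ_counts / sum(occ_counts)
  occ_time <- occ_counts / frame_rate
  f <- vapply(masks, function(m) {
    hits <- tabulate(pbins[train][m[train]], n_bins)
    ifelse(occ_time > 0, hits / pmax(occ_time, 1e-12), 0) + rate_floor
  }, numeric(n_bins))                       # n_bins x M
  log_f <- log(f)
  sum_f <- rowSums(f)
  log_prior <- ifelse(prior > 0, log(prior), -Inf)
  frames_per_win <- max(1L, round(window * frame_rate))
  wins <- split(test, ceiling(seq_along(test) / frames_per_win))
  M <- length(masks)
  out <- lapply(wins, function(w) {
    nj <- vapply(seq_len(M), function(j) sum(masks[[j]][w]), 1L)
    lp <- log_prior - window * sum_f
    if (any(nj > 0L)) {
      lp <- lp + as.numeric(log_f[, nj > 0L, drop = FALSE] %*% nj[nj > 0L])
    }
    flagged <- !any(is.finite(lp))
    if (flagged) lp <- log_prior
    dec <- which.max(lp)
    truth <- as.integer(round(mean(pbins[w])))
    data.frame(decoded_bin = dec, truth_bin = truth,
               abs_error_pct = abs(dec - truth) / n_bins * 100,
               flagged = flagged)
  })
  windows <- do.call(rbind, out)
  structure(list(windows = windows,
                 median_abs_error_pct = stats::median(windows$abs_error_pct),
                 window = window, train_fraction = train_fraction,
                 n_bins = n_bins),
            class = "decode_result")
}

#' Split a population into information quantile groups
#'
#' Partitions neurons into `n_quantiles` equal-count groups by the given
#' metric, ties broken by stable neuron order (rank with `ties.method =
#' "first"`), so any strictly monotone relabeling of the metric leaves
#' the partition unchanged.
#'
#' @param result data frame of per-neuron estimates (e.g. from
#'   [run_library()]).
#' @param metric_column column to rank by.
#' @param n_quantiles number of groups (default 3).
#' @return Integer vector of group labels (1 = lowest metric).
#' @export
quantile_split <- function(result, metric_column, n_quantiles = 3) {
  x <- result[[metric_column]]
  if (length(x) < n_quantiles) {
    stop("need at least n_quantiles neurons", call. = FALSE)
  }
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * n_quantiles))
}
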