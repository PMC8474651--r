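#' Simulate a library of mock neurons end to end
#'
#' For each neuron: sample a ground-truth (rate, information) target,
#' optimize a spline rate map to hit it, synthesize linear-track behavior
#' of a duration drawn uniformly from `session_minutes_range`, simulate
#' inhomogeneous Poisson spikes at 1 kHz, bin them to 30 Hz frames,
#' synthesize a noisy indicator dF/F trace, and compute the rate-map
#' information estimators from both the spike and the fluorescence frame
#' series.  By default the estimators use all frames of the session --
#' the same convention under which the ground truth is defined (the CIF
#' is normalized over the entire session); set `use_run_mask = TRUE` to
#' restrict the maps to running periods instead.
#' Fully reproducible from the master seed: each neuron gets an
#' independently derived seed, so any execution order yields the same
#' table.
#'
#' @param n_neurons number of mock neurons.
#' @param indicator an indicator name from [indicator_presets()] or a
#'   `fluor_kernel`.
#' @param session_minutes_range session duration range in minutes
#'   (uniform; default 3--60).
#' @param noise_sd additive dF/F noise SD (default 0.15).
#' @param frame_rate imaging frame rate, Hz.
#' @param n_bins spatial bins for the estimators (default 60).
#' @param nonlinearity apply the saturating summation nonlinearity to
#'   the dF/F trace before estimation.
#' @param include_ksg,include_binned also run the KSG / binned
#'   estimators on the fluorescence trace (slower; off by default).
#' @param use_run_mask restrict occupancy/activity maps to run periods
#'   (default `FALSE`).
#' @param seed master RNG seed.
#' @param behavior_fn function `(duration_s, seed)` returning a
#'   [behavior_trace()]; defaults to [synth_behavior()] with its default
#'   track statistics.
#' @param progress print a dot every 50 neurons.
#' @return Data frame with one row per neuron: ground truth (`i_ap_true`,
#'   `i_s_true`, `mean_rate`), session descriptors (`duration_s`,
#'   `n_laps`), the estimates (`smgm_s_spike`, `smgm_ap_spike`,
#'   `smgm_s_fluor`, `smgm_ap_fluor`, optionally `ksg_fluor`,
#'   `binned_uniform_fluor`, `binned_occupancy_fluor`), the per-neuron
#'   `seed`, and a convergence `flag`.
#' @export
run_library <- function(n_neurons, indicator = "gCaMP6f",
                        session_minutes_range = c(3, 60), noise_sd = 0.15,
                        frame_rate = 30, n_bins = 60, nonlinearity = FALSE,
                        include_ksg = FALSE, include_binned = FALSE,
                        use_run_mask = FALSE,
                        seed = NULL, behavior_fn = NULL, progress = FALSE) {
  if (n_neurons < 1) stop("n_neurons must be >= 1", call. = FALSE)
  kernel <- if (inherits(indicator, "fluor_kernel")) indicator
            else preset_kernel(indicator)
  seeds <- derive_seeds(seed %||% 1L, n_neurons)
  targets <- sample_targets(n_neurons, seed = (seed %||% 1L) + 1L)
  if (is.null(behavior_fn)) {
    behavior_fn <- function(duration_s, seed) {
      synth_behavior(duration_s, seed = seed)
    }
  }
  rows <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    rows[[i]] <- simulate_neuron(
      i, targets[i, ], kernel, session_minutes_range, noise_sd,
      frame_rate, n_bins, nonlinearity, include_ksg, include_binned,
      seeds[i], behavior_fn, use_run_mask)
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}

# One neuron of the library pipeline; failures come back as flagged rows.
simulate_neuron <- function(id, target, kernel, session_minutes_range,
                            noise_sd, frame_rate, n_bins, nonlinearity,
                            include_ksg, include_binned, seed, behavior_fn,
                            use_run_mask = FALSE) {
  row <- data.frame(neuron_id = id, seed = seed,
                    sampled_domain = target$sampled_domain,
                    i_ap_true = NA_real_, i_s_true = NA_real_,
                    mean_rate = target$mean_rate,
                    duration_s = NA_real_, n_laps = NA_integer_,
                    smgm_s_spike = NA_real_, smgm_ap_spike = NA_real_,
                    smgm_s_fluor = NA_real_, smgm_ap_fluor = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  if (include_ksg) row$ksg_fluor <- NA_real_
  if (include_binned) {
    row$binned_uniform_fluor <- NA_real_
    row$binned_occupancy_fluor <- NA_real_
  }
  out <- try({
    sub <- derive_seeds(seed, 4L)
    map <- optimize_ratemap(target$i_ap, mean_rate = target$mean_rate,
                            seed = sub[1])
    row$i_ap_true <- map$achieved_info_ap
    row$i_s_true <- map$achieved_info_ap * target$mean_rate
    dur <- with_seed(sub[2], stats::runif(1, session_minutes_range[1],
                                          session_minutes_range[2])) * 60
    trace <- behavior_fn(dur, sub[2])
    row$duration_s <- session_duration(trace)
    row$n_laps <- length(trace$lap_starts) + 1L
    cif <- build_cif(map, trace, mean_rate = target$mean_rate)
    train <- generate_spikes(cif, seed = sub[3])
    frames <- bin_to_frames(train, frame_rate)
    dff <- synth_fluorescence(train, kernel, noise_sd = noise_sd,
                              frame_rate = frame_rate, seed = sub[4])
    if (nonlinearity) dff <- apply_nonlinearity(dff)
    mask <- if (use_run_mask) run_mask(trace) else NULL
    maps_spk <- spatial_maps(frames, trace, mask, n_bins)
    maps_flu <- spatial_maps(dff, trace, mask, n_bins)
    row$smgm_s_spike <- smgm_bits_per_second(maps_spk)$value
    row$smgm_ap_spike <- smgm_bits_per_ap(maps_spk)$value
    row$smgm_s_fluor <- smgm_bits_per_second(maps_flu)$value
    row$smgm_ap_fluor <- smgm_bits_per_ap(maps_flu)$value
    if (include_ksg || include_binned) {
      pbins <- frame_position_bins(trace, length(dff$values), frame_rate,
                                   n_bins)
      if (include_ksg) {
        centers <- (seq_along(dff$values) - 0.5) / frame_rate
        pos <- stats::approx(trace$timestamps, trace$position,
                             xout = centers, rule = 2)$y
        row$ksg_fluor <- ksg_mi(dff$values, pos, k = 5,
                                frame_rate = frame_rate,
                                seed = sub[4])$value
      }
      if (include_binned) {
        row$binned_uniform_fluor <-
          binned_mi(dff$values, pbins, 10, "uniform", frame_rate)$value
        row$binned_occupancy_fluor <-
          binned_mi(dff$values, pbins, 10, "occupancy", frame_rate)$value
      }
    }
    NULL
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    row$flag <- conditionMessage(attr(out, "condition"))
  }
  row
}

#' Error summary for an estimate column against ground truth
#'
#' Per-neuron error statistics in native units and percent (percent
#' error = 100 (est - truth)/truth; rows with zero truth are excluded
#' from percent statistics only), an ordinary least-squares linear fit
#' of estimate on truth, a saturating-exponential fit
#' \eqn{y = A(1 - e^{-x/B})}, and a nested Gaussian likelihood-ratio
#' test (1 df) comparing the two.
#'
#' @param result a [run_library()] table (flagged rows dropped).
#' @param estimate_column,truth_column column names.
#' @return List of class `error_summary`: `mean_error`, `sd_error`,
#'   `mean_pct_error`, `sd_pct_error`, `mean_abs_error`,
#'   `mean_abs_pct_error`, `linear_fit` (slope, intercept, r_squared,
#'   standard errors), `satexp_fit` (amplitude, rate constant,
#'   asymptote), `lrt_chi2`, `lrt_p`, `n`.
#' @export
summarize_errors <- function(result, estimate_column, truth_column) {
  ok <- result$flag == "" & is.finite(result[[estimate_column]]) &
    is.finite(result[[truth_column]])
  est <- result[[estimate_column]][ok]
  truth <- result[[truth_column]][ok]
  if (length(est) < 3L) stop("need at least 3 usable rows", call. = FALSE)
  err <- est - truth
  nz <- truth != 0
  pct <- 100 * err[nz] / truth[nz]
  fit <- stats::lm(est ~ truth)
  sf <- suppressWarnings(summary(fit))
  cf <- sf$coefficients
  linear_fit <- list(slope = cf["truth", 1], intercept = cf["(Intercept)", 1],
                     slope_se = cf["truth", 2],
                     intercept_se = cf["(Intercept)", 2],
                     r_squared = sf$r.squared)
  satexp <- tryCatch(suppressWarnings({
    nfit <- stats::nls(est ~ A * (1 - exp(-truth / B)),
                       start = list(A = max(abs(est)) + 1e-6,
                                    B = max(mean(truth), 1e-3)),
                       control = stats::nls.control(maxiter = 200,
                                                    warnOnly = TRUE))
    co <- stats::coef(nfit)
    list(amplitude = co[["A"]], rate = co[["B"]], asymptote = co[["A"]],
         rss = sum(stats::resid(nfit)^2))
  }), error = function(e) NULL)
  lrt_chi2 <- lrt_p <- NA_real_
  if (!is.null(satexp)) {
    rss_lin <- sum(stats::resid(fit)^2)
    n <- length(est)
    lrt_chi2 <- max(n * log(rss_lin / satexp$rss), 0)
    lrt_p <- stats::pchisq(lrt_chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(
    mean_error = mean(err), sd_error = stats::sd(err),
    mean_pct_error = mean(pct), sd_pct_error = stats::sd(pct),
    mean_abs_error = mean(abs(err)), mean_abs_pct_error = mean(abs(pct)),
    linear_fit = linear_fit,
    satexp_fit = satexp[c("amplitude", "rate", "asymptote")],
    lrt_chi2 = lrt_chi2, lrt_p = lrt_p, n = length(est)),
    class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary (n=%d): mean %.3g (%.3g%%), |mean| %.3g (%.3g%%), slope %.3g, R2 %.3g>\n",
    x$n, x$mean_error, x$mean_pct_error, x$mean_abs_error,
    x$mean_abs_pct_error, x$linear_fit$slope, x$linear_fit$r_squared))
  invisible(x)
}

#' Kernel-height sweep
#'
#' Simulates `n` fluorescence traces with GCaMP6f-shaped kernels whose
#' heights are drawn uniformly over `height_range` (width and shape
#' fixed), then regresses the per-trace bits/s percent error on kernel
#' height (linear) and summarizes the bits/AP percent error, which
#' should show no height dependence.
#'
#' @param n number of traces.
#' @param height_range kernel height range in dF/F (default 0--3).
#' @param base_kernel kernel supplying the shape (default gCaMP6f).
#' @param session_minutes_range,noise_sd,seed as in [run_library()].
#' @return List with the per-trace `table`, the bits/s percent-error
#'   linear fit vs height (`fit_s`: intercept, slope, and their SEs),
#'   and the bits/AP fit (`fit_ap`).
#' @export
kernel_height_sweep <- function(n, height_range = c(0, 3),
                                base_kernel = preset_kernel("gCaMP6f"),
                                session_minutes_range = c(3, 60),
                                noise_sd = 0.15, seed = NULL) {
  heights <- with_seed(seed %||% 1L,
                       stats::runif(n, height_range[1], height_range[2]))
  rows <- vector("list", n)
  seeds <- derive_seeds((seed %||% 1L) + 7L, n)
  targets <- sample_targets(n, seed = (seed %||% 1L) + 13L)
  for (i in seq_len(n)) {
    k <- base_kernel
    k$height <- heights[i]
    rows[[i]] <- simulate_neuron(
      i, targets[i, ], k, session_minutes_range, noise_sd, 30, 60,
      FALSE, FALSE, FALSE, seeds[i],
      function(duration_s, seed) synth_behavior(duration_s, seed = seed))
    rows[[i]]$height <- heights[i]
  }
  tab <- do.call(rbind, rows)
  ok <- tab$flag == "" & tab$i_s_true > 0
  pct_s <- 100 * (tab$smgm_s_fluor[ok] - tab$i_s_true[ok]) / tab$i_s_true[ok]
  pct_ap <- 100 * (tab$smgm_ap_fluor[ok] - tab$i_ap_true[ok]) /
    tab$i_ap_true[ok]
  h <- tab$height[ok]
  fs <- stats::lm(pct_s ~ h)
  fa <- stats::lm(pct_ap ~ h)
  lin <- function(f) {
    cf <- summary(f)$coefficients
    list(intercept = cf[1, 1], intercept_se = cf[1, 2],
         slope = cf[2, 1], slope_se = cf[2, 2],
         slope_p = cf[2, 4], r_squared = summary(f)$r.squared)
  }
  list(table = tab, fit_s = lin(fs), fit_ap = lin(fa))
}

#' Kernel-width sweep
#'
#' Simulates `n` traces whose kernels span a range of durations: rise
#' times uniform on `rise_range`, fall times uniform between the rise
#' time and `fall_max`, height fixed.  Returns the per-trace table with
#' achieved kernel widths and percent errors for both fluorescence
#' metrics, plus per-width-bin mean percent errors.
#'
#' @param n number of traces.
#' @param rise_range rise-time range, seconds (default 0.001--1).
#' @param fall_max maximum fall time, seconds (default 2).
#' @param height fixed kernel height, dF/F.
#' @param n_width_bins number of width bins for the summary.
#' @param session_minutes_range,noise_sd,seed as in [run_library()].
#' @return List with `table` and `by_width` (width-bin midpoints, mean
#'   percent error of each metric).
#' @export
kernel_width_sweep <- function(n, rise_range = c(0.001, 1), fall_max = 2,
                               height = 0.190, n_width_bins = 8,
                               session_minutes_range = c(3, 60),
                               noise_sd = 0.15, seed = NULL) {
  par <- with_seed(seed %||% 1L, {
    rise <- stats::runif(n, rise_range[1], rise_range[2])
    fall <- stats::runif(n, rise, fall_max)
    list(rise = rise, fall = fall)
  })
  seeds <- derive_seeds((seed %||% 1L) + 7L, n)
  targets <- sample_targets(n, seed = (seed %||% 1L) + 13L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- tryCatch(make_kernel(height, par$rise[i], par$fall[i]),
                  error = function(e) NULL)
    if (is.null(k)) next
    rows[[i]] <- simulate_neuron(
      i, targets[i, ], k, session_minutes_range, noise_sd, 30, 60,
      FALSE, FALSE, FALSE, seeds[i],
      function(duration_s, seed) synth_behavior(duration_s, seed = seed))
    rows[[i]]$kernel_width <- k$width
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  ok <- tab$flag == "" & tab$i_s_true > 0
  tab <- tab[ok, ]
  tab$pct_s <- 100 * (tab$smgm_s_fluor - tab$i_s_true) / tab$i_s_true
  tab$pct_ap <- 100 * (tab$smgm_ap_fluor - tab$i_ap_true) / tab$i_ap_true
  wb <- cut(tab$kernel_width, breaks = n_width_bins)
  by_width <- data.frame(
    width_mid = tapply(tab$kernel_width, wb, mean),
    mean_pct_s = tapply(tab$pct_s, wb, mean),
    mean_pct_ap = tapply(tab$pct_ap, wb, mean))
  list(table = tab, by_width = by_width[is.finite(by_width$width_mid), ])
}

#' Recording-density summaries: error vs mean rate and lap count
#'
#' Bins a library table by mean firing rate and by lap count and reports
#' the mean and mean-absolute percent error in each bin for all four
#' rate-map estimator variants (spike and fluorescence, bits/s and
#' bits/AP).
#'
#' @param result a [run_library()] table.
#' @param rate_breaks,lap_breaks bin edges.
#' @return List of two data frames, `by_rate` and `by_laps`.
#' @export
density_sweep <- function(result,
                          rate_breaks = c(0.1, 0.3, 0.6, 1, 2, 5, 10, 30),
                          lap_breaks = c(0, 5, 11, 25, 50, 100, 200, Inf)) {
  tab <- result[result$flag == "" & result$i_s_true > 0, ]
  pct <- data.frame(
    s_spike = 100 * (tab$smgm_s_spike - tab$i_s_true) / tab$i_s_true,
    ap_spike = 100 * (tab$smgm_ap_spike - tab$i_ap_true) / tab$i_ap_true,
    s_fluor = 100 * (tab$smgm_s_fluor - tab$i_s_true) / tab$i_s_true,
    ap_fluor = 100 * (tab$smgm_ap_fluor - tab$i_ap_true) / tab$i_ap_true)
  summarize_by <- function(groups) {
    out <- data.frame(group = levels(groups))
    for (v in names(pct)) {
      out[[paste0("mean_", v)]] <-
        as.numeric(tapply(pct[[v]], groups, mean))
      out[[paste0("abs_", v)]] <-
        as.numeric(tapply(abs(pct[[v]]), groups, mean))
    }
    out
  }
  list(by_rate = summarize_by(cut(tab$mean_rate, rate_breaks)),
       by_laps = summarize_by(cut(tab$n_laps, lap_breaks)))
}

#' Bin-count sweep
#'
#' Simulates `n` neurons once, then recomputes the fluorescence
#' estimators at each requested spatial bin count, giving an error
#' surface over (ground truth, bin count).
#'
#' @param n number of neurons.
#' @param bins vector of spatial bin counts (each >= 2).
#' @param indicator indicator preset name or `fluor_kernel`.
#' @param session_minutes_range,noise_sd,seed as in [run_library()].
#' @return Data frame with one row per (neuron, bin count):
#'   `neuron_id`, `n_bins`, `i_ap_true`, `i_s_true`, `smgm_s_fluor`,
#'   `smgm_ap_fluor`, `pct_s`, `pct_ap`.
#' @export
bin_count_sweep <- function(n, bins = c(2, 5, 10, 20, 40, 60),
                            indicator = "gCaMP6f",
                            session_minutes_range = c(3, 60),
                            noise_sd = 0.15, seed = NULL) {
  if (any(bins < 2)) stop("all bin counts must be >= 2", call. = FALSE)
  kernel <- if (inherits(indicator, "fluor_kernel")) indicator
            else preset_kernel(indicator)
  seeds <- derive_seeds(seed %||% 1L, n)
  targets <- sample_targets(n, seed = (seed %||% 1L) + 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- try({
      sub <- derive_seeds(seeds[i], 4L)
      map <- optimize_ratemap(targets$i_ap[i],
                              mean_rate = targets$mean_rate[i],
                              seed = sub[1])
      dur <- with_seed(sub[2], stats::runif(1, session_minutes_range[1],
                                            session_minutes_range[2])) * 60
      trace <- synth_behavior(dur, seed = sub[2])
      cif <- build_cif(map, trace, mean_rate = targets$mean_rate[i])
      train <- generate_spikes(cif, seed = sub[3])
      dff <- synth_fluorescence(train, kernel, noise_sd = noise_sd,
                                seed = sub[4])
      mask <- run_mask(trace)
      i_s_true <- map$achieved_info_ap * targets$mean_rate[i]
      rows <- lapply(bins, function(nb) {
        mp <- spatial_maps(dff, trace, mask, nb)
        s <- smgm_bits_per_second(mp)$value
        ap <- smgm_bits_per_ap(mp)$value
        data.frame(neuron_id = i, n_bins = nb,
                   i_ap_true = map$achieved_info_ap, i_s_true = i_s_true,
                   smgm_s_fluor = s, smgm_ap_fluor = ap,
                   pct_s = 100 * (s - i_s_true) / i_s_true,
                   pct_ap = 100 * (ap - map$achieved_info_ap) /
                     map$achieved_info_ap)
      })
      do.call(rbind, rows)
    }, silent = TRUE)
    if (!inherits(res, "try-error")) out[[i]] <- res
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
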