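test_that("pure noise yields essentially no significant transients", {
  set.seed(81)
  noise <- frame_series(rnorm(20000, 0, 0.15), 30, kind = "dff")
  tm <- detect_transients(noise, noise_sd_estimate = 0.15)
  expect_lt(mean(tm$mask), 1e-4 * 10)   # far below the 2-sigma excursion rate
})

test_that("an injected transient is flagged and zero traces give empty masks", {
  set.seed(82)
  x <- rnorm(20000, 0, 0.15)
  idx <- 5000:5030                       # ~1 s at 30 Hz, 5 sigma
  x[idx] <- x[idx] + 0.75
  tm <- detect_transients(frame_series(x, 30, kind = "dff"),
                          noise_sd_estimate = 0.15)
  expect_true(any(tm$mask[idx]))
  zero <- detect_transients(frame_series(rep(0, 2000), 30, kind = "dff"))
  expect_false(any(zero$mask))
})

test_that("sparse negative statistics trigger the Gaussian-null fallback", {
  set.seed(95)
  # short all-positive trace: a big transient but almost no negative events
  x <- abs(rnorm(1200, 0, 0.02))
  x[300:320] <- x[300:320] + 1
  expect_warning(
    tm <- detect_transients(frame_series(x, 30, kind = "dff"),
                            noise_sd_estimate = 0.15),
    "Gaussian-null")
  expect_true(any(tm$mask[300:320]))
})

# Shared positive-control neuron: a clear 40-cm field, long session.
place_cell_bundle <- function(seed = 83) {
  tr <- synth_behavior(600, seed = seed)
  nodes <- data.frame(x = c(0, 0.4, 0.5, 0.6, 1), y = c(-3, 1.5, 4, 1.5, -3))
  m <- rate_map("spline", nodes = nodes, mean_rate = 2)
  cif <- build_cif(m, tr, mean_rate = 2)
  train <- generate_spikes(cif, seed = seed + 1)
  dff <- synth_fluorescence(train, preset_kernel("gCaMP6f"), seed = seed + 2)
  list(trace = tr, dff = dff)
}

test_that("place-field detection finds a real field and rejects a null", {
  b <- place_cell_bundle()
  pf <- find_place_fields(b$dff, b$trace, n_boot = 200, seed = 84)
  expect_true(pf$is_place_cell)
  expect_gte(nrow(pf$fields), 1)
  expect_true(all(pf$fields$width_cm >= 20 & pf$fields$width_cm <= 120))
  # width rule: a field narrower than 20 cm (< 4 bins) is rejected
  expect_true(all(pf$fields$end_bin - pf$fields$start_bin + 1 >= 4))

  # null neuron: noise-only trace rarely produces fields
  set.seed(85)
  noise <- frame_series(rnorm(length(b$dff$values), 0, 0.15), 30,
                        kind = "dff")
  pf0 <- find_place_fields(noise, b$trace, n_boot = 200, seed = 86)
  expect_false(pf0$is_place_cell && nrow(pf0$fields) > 1)
})

test_that("decoder is exact for delta-tuned neurons", {
  # one neuron active only in bin 30, behavior sweeping uniformly
  tr <- sweep_trace(600)
  n_frames <- floor(600 * 30)
  pb <- frame_position_bins(tr, n_frames, 30, 60)
  mask <- pb == 30
  dec <- bayes_decode(list(mask), tr, window = 0.1, train_fraction = 0.8)
  hit <- dec$windows[dec$windows$truth_bin == 30, ]
  expect_true(nrow(hit) > 0)
  expect_true(all(abs(hit$decoded_bin - 30) <= 1))
})

test_that("flat maps decode to the occupancy prior argmax", {
  tr <- short_trace()
  n_frames <- floor(300 * 30)
  never <- rep(FALSE, n_frames)
  dec <- bayes_decode(list(never), tr, window = 0.1)
  pb <- frame_position_bins(tr, n_frames, 30, 60)
  train_bins <- pb[seq_len(floor(0.8 * n_frames))]
  prior_argmax <- as.integer(names(which.max(table(train_bins))))
  expect_true(all(dec$windows$decoded_bin == prior_argmax))
})

test_that("decoding error decreases with population size", {
  tr <- synth_behavior(600, seed = 87)
  n_frames <- floor(600 * 30)
  pb <- frame_position_bins(tr, n_frames, 30, 60)
  set.seed(88)
  make_neuron <- function() {
    center <- sample.int(60, 1)
    active <- abs(pb - center) <= 3 & runif(n_frames) < 0.25
    active
  }
  pop <- replicate(60, make_neuron(), simplify = FALSE)
  errs <- vapply(c(5, 20, 60), function(m)
    bayes_decode(pop[seq_len(m)], tr)$median_abs_error_pct, 1)
  expect_true(errs[3] < errs[1])
  expect_true(errs[3] <= errs[2] + 1)
})

test_that("quantile splits are rank-based, stable, and balanced", {
  df <- data.frame(mi = c(5, 1, 9, 3, 7, 2, 8, 4, 6))
  g <- quantile_split(df, "mi", 3)
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_identical(quantile_split(data.frame(mi = exp(df$mi)), "mi", 3), g)
  expect_equal(g[df$mi <= 3], rep(1L, 3))
  expect_error(quantile_split(df[1:2, , drop = FALSE], "mi", 3), "at least")
})
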