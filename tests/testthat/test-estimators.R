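test_that("spatial maps satisfy weighted-mean consistency and occupancy norm", {
  m <- optimize_ratemap(1.8, mean_rate = 6, seed = 51)
  tr <- short_trace()
  cif <- build_cif(m, tr, mean_rate = 6)
  fr <- bin_to_frames(generate_spikes(cif, seed = 52))
  maps <- spatial_maps(fr, tr, run_mask(tr), 60)
  expect_equal(sum(maps$occupancy), 1, tolerance = 1e-12)
  expect_equal(sum(maps$occupancy * maps$activity), maps$overall_mean,
               tolerance = 1e-10)
  expect_error(spatial_maps(fr, tr, NULL, 1), ">= 2")
})

test_that("uniform sweep gives near-flat occupancy", {
  tr <- sweep_trace()
  vals <- frame_series(rep(1, floor(300 * 30)), 30, kind = "dff")
  maps <- spatial_maps(vals, tr, NULL, 60)
  expect_lt(max(abs(maps$occupancy - 1 / 60)), 0.25 / 60)
  expect_equal(maps$activity[maps$occupied],
               rep(1, sum(maps$occupied)), tolerance = 1e-12)
})

test_that("rate-map estimators reproduce hand-computed examples", {
  # flat map carries no information
  flat <- manual_maps(rep(1 / 60, 60), rep(2, 60), "hz")
  expect_equal(smgm_bits_per_second(flat)$value, 0, tolerance = 1e-12)
  # two bins: p = (1/2, 1/2), rates (2, 0) -> 0.5 * 2 * log2(2) = 1 bit/s
  two <- manual_maps(c(0.5, 0.5), c(2, 0), "hz")
  expect_equal(smgm_bits_per_second(two)$value, 1, tolerance = 1e-12)
  expect_equal(smgm_bits_per_ap(two)$value, 1, tolerance = 1e-12)
  # all rate concentrated in one of 60 bins at unit mean -> log2(60)
  conc <- manual_maps(rep(1 / 60, 60), c(60, rep(0, 59)), "hz")
  expect_equal(smgm_bits_per_second(conc)$value, log2(60), tolerance = 1e-12)
  expect_equal(smgm_bits_per_ap(conc)$value, log2(60), tolerance = 1e-12)
})

test_that("rate-map estimators match the direct-sum oracle on random maps", {
  set.seed(53)
  for (i in 1:20) {
    nb <- sample(5:80, 1)
    p <- runif(nb); p <- p / sum(p)
    lam <- rexp(nb) * sample(c(1, 1, 0), nb, replace = TRUE)
    if (sum(lam) == 0) lam[1] <- 1
    maps <- manual_maps(p, lam, "hz")
    expect_equal(smgm_bits_per_second(maps)$value,
                 max(smgm_oracle_sec(p, lam), 0), tolerance = 1e-10)
  }
})

test_that("bits/AP is the bits/s value normalized by the overall mean and is scale-free", {
  set.seed(54)
  p <- runif(60); p <- p / sum(p)
  lam <- rexp(60)
  maps <- manual_maps(p, lam, "hz")
  expect_equal(smgm_bits_per_ap(maps)$value,
               smgm_bits_per_second(maps)$value / maps$overall_mean,
               tolerance = 1e-12)
  for (kf in c(0.01, 0.5, 7, 1000)) {
    scaled <- manual_maps(p, kf * lam, "hz")
    expect_equal(smgm_bits_per_ap(scaled)$value,
                 smgm_bits_per_ap(maps)$value, tolerance = 1e-10)
  }
})

test_that("rate-map information is non-negative and bounded by log2(n_bins)", {
  set.seed(55)
  for (i in 1:30) {
    p <- runif(60); p <- p / sum(p)
    lam <- rexp(60)^2
    maps <- manual_maps(p, lam, "hz")
    v <- smgm_bits_per_ap(maps)$value
    expect_gte(v, 0)
    expect_lte(v, log2(60) + 1e-9)
  }
})

test_that("binned estimator equals a brute-force joint-histogram oracle", {
  set.seed(56)
  n <- 3000
  pos <- sample.int(60, n, replace = TRUE)
  act <- rnorm(n) + 0.05 * pos
  for (scheme in c("uniform", "occupancy")) {
    est <- binned_mi(act, pos, 10, scheme, frame_rate = 30)
    breaks <- if (scheme == "uniform") {
      seq(min(act), max(act), length.out = 11)
    } else {
      unique(quantile(act, seq(0, 1, 0.1), names = FALSE))
    }
    ab <- .bincode(act, breaks, right = TRUE, include.lowest = TRUE)
    expect_equal(est$value / 30, plugin_mi_oracle(pos, ab), tolerance = 1e-12)
  }
  expect_equal(binned_mi(rep(2, 100), sample.int(60, 100, TRUE))$value, 0)
})

test_that("shuffled data shows only the plug-in bias predicted by Miller-Madow", {
  set.seed(57)
  n <- 20000
  pos <- sample.int(60, n, replace = TRUE)
  act <- rnorm(n)                       # independent of position
  est <- binned_mi(act, pos, 10, "uniform", frame_rate = 1)$value
  mm_bias <- (60 - 1) * (10 - 1) / (2 * n * log(2))
  expect_lt(abs(est - mm_bias), mm_bias)   # same order as the predicted bias
})

test_that("KSG estimator is near zero for independent samples", {
  set.seed(58)
  est <- ksg_mi(rnorm(2000), rnorm(2000), k = 5, frame_rate = 1, seed = 1)
  expect_lt(abs(est$value), 0.05)
})

test_that("KSG recovers the closed-form Gaussian MI", {
  set.seed(59)
  n <- 5000; rho <- 0.9
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  truth <- -0.5 * log2(1 - rho^2)
  est <- ksg_mi(x, y, k = 5, frame_rate = 1, seed = 2)
  expect_lt(abs(est$value - truth), 0.05)
})

test_that("KSG estimate is invariant under monotone rescaling", {
  set.seed(60)
  n <- 1500
  x <- rnorm(n); y <- 0.8 * x + 0.6 * rnorm(n)
  e1 <- ksg_mi(x, y, k = 5, frame_rate = 1, seed = 3)$value
  e2 <- ksg_mi(exp(x), y^3, k = 5, frame_rate = 1, seed = 3)$value
  expect_lt(abs(e1 - e2), 0.1)
})

test_that("analytic approximations have the stated limits", {
  expect_equal(analytic_bits_per_ap(2.5, v = 0.07, tau = 0)$value, 2.5,
               tolerance = 1e-12)
  taus <- seq(0, 2, by = 0.1)
  vals <- vapply(taus, function(tt)
    analytic_bits_per_ap(3, v = 0.07, tau = tt)$value, 1)
  expect_true(all(diff(vals) < 0))
  expect_equal(analytic_bits_per_second(5, mean_rate = 2, v = 0.07,
                                        tau = 0)$value, 0, tolerance = 1e-12)
})

test_that("fluorescence bits/AP is invariant to kernel height at zero noise", {
  m <- optimize_ratemap(2, mean_rate = 4, seed = 61)
  tr <- short_trace()
  cif <- build_cif(m, tr, mean_rate = 4)
  train <- generate_spikes(cif, seed = 62)
  vals <- vapply(c(0.05, 0.19, 1, 3), function(h) {
    k <- preset_kernel("gCaMP6f"); k$height <- h
    dff <- synth_fluorescence(train, k, noise_sd = 0)
    smgm_bits_per_ap(spatial_maps(dff, tr, NULL, 60))$value
  }, 1)
  expect_lt(max(vals) - min(vals), 1e-10)
})
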