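test_that("fitted rate constants satisfy the rise/fall targets", {
  presets <- indicator_presets()
  for (i in seq_len(nrow(presets))) {
    fit <- fit_kernel_rates(presets$rise[i], presets$fall[i])
    expect_lt(abs(double_exp(presets$rise[i], fit$a, fit$b) - 1), 1e-3)
    expect_lt(abs(double_exp(presets$rise[i] + presets$fall[i],
                             fit$a, fit$b) - 0.5), 1e-3)
  }
})

test_that("doubling both times halves the rate constants", {
  f1 <- fit_kernel_rates(0.042, 0.142)
  f2 <- fit_kernel_rates(0.084, 0.284)
  expect_equal(f2$a, f1$a / 2, tolerance = 1e-3)
  expect_equal(f2$b, f1$b / 2, tolerance = 1e-3)
})

test_that("fitted rates agree with a brute-force grid search oracle", {
  rise <- 0.042; fall <- 0.142
  fit <- fit_kernel_rates(rise, fall)
  obj <- function(a, b) (1 - double_exp(rise, a, b))^2 +
    (0.5 - double_exp(rise + fall, a, b))^2
  grid_a <- seq(fit$a * 0.5, fit$a * 2, length.out = 200)
  grid_b <- seq(fit$b * 0.5, fit$b * 2, length.out = 200)
  vals <- outer(grid_a, grid_b, Vectorize(obj))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(grid_a[best[1]] - fit$a) / fit$a, 0.02)
  expect_lt(abs(grid_b[best[2]] - fit$b) / fit$b, 0.02)
})

test_that("kernel width closed form matches a numeric root-find", {
  for (nm in c("gCaMP6f", "gCaMP6s", "iGluSnfR-A184S")) {
    k <- preset_kernel(nm)
    H <- function(f) {
      w <- 2 * pi * f
      k$a * k$b / sqrt((k$a^2 + w^2) * (k$b^2 + w^2))
    }
    f_half <- uniroot(function(f) H(f) - 0.5, c(1e-6, 1e3), tol = 1e-12)$root
    expect_lt(abs(1 / f_half - k$width), 1e-9)
  }
})

test_that("peak normalization holds on a dense grid", {
  k <- preset_kernel("jRGECO1a")
  tt <- seq(0, 3, by = 1e-4)
  expect_lt(abs(max(double_exp(tt, k$a, k$b)) - 1), 1e-6)
})

test_that("sweep kernels recover a preset's rates from its own targets", {
  k6f <- preset_kernel("gCaMP6f")
  sk <- make_sweep_kernel(k6f$width, 0.042, 0.142)
  expect_lt(abs(sk$a - k6f$a) / k6f$a, 0.01)
  expect_lt(abs(sk$b - k6f$b) / k6f$b, 0.01)
  expect_lt(abs(sk$width - k6f$width) / k6f$width, 0.05)
  expect_lte(sk$rise, sk$half_fall)
})

test_that("single-spike trace peaks at the kernel height", {
  train <- spike_train(1.0, duration = 10)
  k <- preset_kernel("gCaMP6f")
  dff <- synth_fluorescence(train, k, noise_sd = 0)
  expect_lt(abs(max(dff$values) - 0.190), 0.01)
  none <- synth_fluorescence(spike_train(numeric(0), duration = 10), k,
                             noise_sd = 0)
  expect_true(all(none$values == 0))
})

test_that("noiseless convolution is linear in the spike train", {
  k <- preset_kernel("gCaMP6s")
  a <- spike_train(c(1, 2.5), duration = 20)
  b <- spike_train(c(4, 4.02, 9), duration = 20)
  ab <- spike_train(sort(c(a$times, b$times)), duration = 20)
  fa <- synth_fluorescence(a, k, noise_sd = 0)$values
  fb <- synth_fluorescence(b, k, noise_sd = 0)$values
  fab <- synth_fluorescence(ab, k, noise_sd = 0)$values
  expect_equal(fab, fa + fb, tolerance = 1e-10)
})

test_that("mean dF/F matches spike count x kernel integral x height", {
  k <- preset_kernel("gCaMP6f")
  set.seed(40)
  train <- spike_train(sort(runif(600, 0, 200)), duration = 220)
  dff <- synth_fluorescence(train, k, noise_sd = 0)
  kernel_integral <- (1 / k$a - 1 / k$b) / double_exp_peak(k$a, k$b)
  expected <- length(train$times) * kernel_integral * k$height / 220
  expect_lt(abs(mean(dff$values) - expected) / expected, 0.01)
})

test_that("saturating nonlinearity has the printed fixed points", {
  expect_equal(apply_nonlinearity(1), 6.264 / 2, tolerance = 1e-12)
  expect_equal(apply_nonlinearity(-1), -6.264 / 2, tolerance = 1e-12)
  expect_identical(apply_nonlinearity(0), 0)
  x <- seq(0.01, 50, length.out = 400)
  y <- apply_nonlinearity(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < 6.264))
})

test_that("dF/F traces round-trip through CSV", {
  k <- preset_kernel("gCaMP6f")
  train <- spike_train(c(0.5, 1.2, 3.3), duration = 5)
  dff <- synth_fluorescence(train, k, noise_sd = 0.15, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_dff(dff, path)
  back <- read_dff(path)
  expect_equal(back$values, dff$values, tolerance = 1e-6)
  expect_equal(back$frame_rate, 30, tolerance = 1e-6)
})
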