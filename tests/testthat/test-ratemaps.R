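test_that("evaluated profiles are normalized and positive", {
  set.seed(11)
  g <- seq(0, 1, length.out = 2001)
  for (i in 1:5) {
    nodes <- data.frame(x = c(0, sort(runif(3)), 1), y = rnorm(5))
    m <- rate_map("spline", nodes = nodes)
    p <- evaluate_ratemap(m, g)
    expect_true(all(p > 0))
    expect_equal(trapz(g, p), 1, tolerance = 1e-6)
  }
  # all node y equal -> constant profile identically 1
  flat <- rate_map("spline",
                   nodes = data.frame(x = c(0, .25, .5, .75, 1), y = rep(2, 5)))
  expect_equal(evaluate_ratemap(flat, c(0, 0.3, 0.97)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("profile evaluation agrees with a 10x-resolution oracle", {
  set.seed(12)
  nodes <- data.frame(x = c(0, sort(runif(3)), 1), y = rnorm(5))
  m <- rate_map("spline", nodes = nodes)
  x <- runif(50)
  expect_equal(evaluate_ratemap(m, x), dense_profile_oracle(m, x),
               tolerance = 1e-6)
})

test_that("invalid node geometry is rejected", {
  bad <- data.frame(x = c(0, 0.6, 0.4, 0.8, 1), y = rnorm(5))
  expect_error(rate_map("spline", nodes = bad), "strictly increasing")
  off_end <- data.frame(x = c(0.1, 0.3, 0.5, 0.7, 1), y = rnorm(5))
  expect_error(rate_map("spline", nodes = off_end), "end nodes")
  expect_error(evaluate_ratemap(rate_map("gaussian", sigma = 0.1), c(-0.5, 2)),
               "\\[0, 1\\]")
})

test_that("differential information: flat map is zero, MC oracle agrees", {
  flat <- rate_map("spline",
                   nodes = data.frame(x = c(0, .2, .5, .8, 1), y = rep(0, 5)))
  expect_equal(differential_information(flat), 0, tolerance = 1e-12)
  set.seed(13)
  nodes <- data.frame(x = c(0, sort(runif(3)), 1), y = rnorm(5) * 1.5)
  m <- rate_map("spline", nodes = nodes)
  mc <- mc_information(m, n = 1e6, seed = 14)
  expect_lt(abs(differential_information(m) - mc$value), 3 * mc$se)
})

test_that("information is scale-invariant in mean_rate", {
  set.seed(15)
  nodes <- data.frame(x = c(0, sort(runif(3)), 1), y = rnorm(5))
  i1 <- differential_information(rate_map("spline", nodes = nodes,
                                          mean_rate = 0.5))
  i2 <- differential_information(rate_map("spline", nodes = nodes,
                                          mean_rate = 25))
  expect_identical(i1, i2)
})

test_that("optimizer hits targets across the range, including both ends", {
  m0 <- optimize_ratemap(0, seed = 1)
  expect_lt(abs(m0$achieved_info_ap - 0), 1e-6)
  for (tg in c(0.04, 0.7, 2, 3.5, 5)) {
    m <- optimize_ratemap(tg, seed = round(100 * tg) + 1L)
    expect_lt(abs(m$achieved_info_ap - tg), 1e-7)
    expect_true(all(diff(m$nodes$x) > 0))
    expect_true(all(m$nodes$x[2:4] > 0 & m$nodes$x[2:4] < 1))
  }
})

test_that("optimizer solution at 5 bits/AP verified by Monte-Carlo oracle", {
  m <- optimize_ratemap(5, seed = 77)
  mc <- mc_information(m, n = 1e6, seed = 78)
  expect_lt(abs(mc$value - 5), 3 * mc$se + 1e-3)
})

test_that("target sampler respects bounds, identity, and coverage", {
  tg <- sample_targets(0)
  expect_equal(nrow(tg), 0)
  expect_error(sample_targets(-1), ">= 0")
  tg <- sample_targets(10000, seed = 3)
  expect_true(all(tg$mean_rate >= 0.1 & tg$mean_rate <= 30))
  expect_true(all(tg$i_ap >= 0 & tg$i_ap <= 6))
  expect_true(all(tg$i_s >= 0 & tg$i_s <= 24 + 1e-9))
  expect_equal(tg$i_s, tg$mean_rate * tg$i_ap)
  # each i_ap decile holds at least 1% of draws
  dec <- table(cut(tg$i_ap, seq(0, 6, length.out = 11)))
  expect_true(all(dec >= 100))
})

test_that("gaussian maps follow the closed-form width", {
  m0 <- gaussian_ratemap(0)
  expect_equal(m0$sigma, exp(-0.5) / sqrt(2 * pi), tolerance = 1e-12)
  expect_true(m0$truncation_warning)   # wide bump clips the track ends
  sig <- vapply(c(0, 1, 2, 3, 4), function(I) gaussian_ratemap(I)$sigma, 1)
  expect_true(all(diff(sig) < 0))      # width strictly decreasing in info
  m3 <- gaussian_ratemap(3)
  expect_false(m3$truncation_warning)
  expect_lt(abs(differential_information(m3) - 3), 0.02)
})

test_that("rate-map libraries round-trip through CSV", {
  maps <- list(optimize_ratemap(1.5, mean_rate = 4, seed = 5),
               gaussian_ratemap(2, mean_rate = 2))
  path <- tempfile(fileext = ".csv")
  write_ratemap_library(maps, path)
  back <- read_ratemap_library(path)
  expect_equal(back[[1]]$achieved_info_ap, maps[[1]]$achieved_info_ap,
               tolerance = 1e-12)
  expect_equal(back[[2]]$sigma, maps[[2]]$sigma, tolerance = 1e-12)
  expect_equal(back[[1]]$mean_rate, 4)
})
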